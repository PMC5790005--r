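make_screen_fixture <- function() {
  # A -> C, B -> D, with readouts C, D and pain node E (isolated input)
  edges <- data.frame(source = c("A", "B", "A"),
                      target = c("C", "D", "E"),
                      sign = c(1, 1, -1), weight = 1)
  model <- make_model(edges, c("A C" = 1.2, "B D" = 1.2, "A E" = 0))
  protection <- phenotype_signature("protection", c("C", "D"), 1, 1)
  pain <- phenotype_signature("pain", "E", 1, 1)
  list(model = model, signatures = list(protection = protection, pain = pain))
}

test_that("drug clamp signatures combine actions and report coverage", {
  fx <- make_screen_fixture()
  d1 <- drug_signature("D1", data.frame(protein = "A", action = 1),
                       all_true_flags)
  d2 <- drug_signature("D2", data.frame(protein = "B", action = -1),
                       all_true_flags)
  sig <- drug_input_signature(list(d1, d2), fx$model)
  expect_equal(sig[["A"]], 1)
  expect_equal(sig[["B"]], -1)

  # both drugs antagonize the same target: sum clipped to -1
  d3 <- drug_signature("D3", data.frame(protein = "A", action = -1),
                       all_true_flags)
  d4 <- drug_signature("D4", data.frame(protein = "A", action = -1),
                       all_true_flags)
  expect_equal(drug_input_signature(list(d3, d4), fx$model)[["A"]], -1)
  # opposite actions on the same target cancel to a zero clamp
  expect_equal(drug_input_signature(list(d1, d3), fx$model)[["A"]], 0)

  # off-map targets are skipped and counted in coverage
  d5 <- drug_signature("D5", data.frame(protein = c("A", "QQ"),
                                        action = c(1, 1)), all_true_flags)
  s5 <- drug_input_signature(d5, fx$model)
  expect_equal(attr(s5, "coverage"), 0.5)
  d6 <- drug_signature("D6", data.frame(protein = "QQ", action = 1),
                       all_true_flags)
  expect_warning(s6 <- drug_input_signature(d6, fx$model), "no target on the map")
  expect_length(s6, 0L)
})

test_that("efficacy and adverse scores follow the directional-agreement formula", {
  sig <- phenotype_signature("protection", c("P1", "P2"), c(1, -1), 1)
  expect_equal(efficacy_score(c(P1 = 1, P2 = -1), sig), 100)
  expect_equal(efficacy_score(c(P1 = 0, P2 = 0), sig), 0)
  # half matched at full magnitude, half at zero -> 50
  expect_equal(efficacy_score(c(P1 = 1, P2 = 0), sig), 50)
  # anti-aligned states clip at zero rather than going negative
  expect_equal(efficacy_score(c(P1 = -1, P2 = 1), sig), 0)
  # weights shift the mean
  wsig <- phenotype_signature("protection", c("P1", "P2"), 1, c(3, 1))
  expect_equal(efficacy_score(c(P1 = 1, P2 = 0), wsig), 75)

  pain <- phenotype_signature("pain", c("P1", "P2"), 1, 1)
  expect_equal(adverse_score(c(P1 = 1, P2 = 1), pain), 100)
  expect_equal(adverse_score(c(P1 = -1, P2 = -1), pain), 0)
  expect_equal(adverse_score(c(P1 = 0.6, P2 = -0.2), pain), 20)
  expect_error(phenotype_signature("x", character(0), 1, 1), "empty")
})

test_that("synergy is pair minus best single, unclipped", {
  expect_equal(synergy_score(60, 20, 25), 35)
  expect_equal(synergy_score(50, 30, 50), 0)
  expect_equal(synergy_score(10, 30, 25), -20)
})

test_that("screening obeys the pair-count law and symmetry", {
  fx <- make_screen_fixture()
  lib <- list(
    drug_signature("Da", data.frame(protein = "A", action = 1), all_true_flags),
    drug_signature("Db", data.frame(protein = "B", action = 1), all_true_flags),
    drug_signature("Dn", data.frame(protein = character(0),
                                    action = numeric(0)), all_true_flags),
    drug_signature("Dx", data.frame(protein = "A", action = -1), all_true_flags))
  res <- screen_combinations(fx$model, lib, fx$signatures)
  expect_equal(nrow(res$pairs), n_pair_count(4))
  expect_equal(nrow(res$singles), 4L)
  # canonical lexicographic storage
  expect_true(all(res$pairs$drug_a < res$pairs$drug_b))
  # permuting the library leaves every pair score identical
  res2 <- screen_combinations(fx$model, rev(lib), fx$signatures)
  expect_equal(res$pairs, res2$pairs)
  expect_equal(n_pair_count(200), 19900)
  expect_equal(n_pair_count(2), 1)

  # null-drug neutrality: pairing with a zero-target drug changes nothing
  singles <- res$singles
  for (other in c("Da", "Db", "Dx")) {
    pr <- res$pairs[res$pairs$drug_a == pmin(other, "Dn") &
                    res$pairs$drug_b == pmax(other, "Dn"), ]
    expect_equal(pr$efficacy_pct,
                 singles$efficacy_pct[singles$drug == other])
    expect_identical(pr$synergy_pts, 0)
  }
})

test_that("candidate filtering enforces thresholds and eligibility", {
  meta <- data.frame(drug = c("A1", "A2", "B1"),
                     safe_profile = c(TRUE, TRUE, TRUE),
                     no_pain_liability = c(TRUE, TRUE, TRUE),
                     no_known_regen_effect = c(TRUE, TRUE, TRUE),
                     crosses_bbb = c(TRUE, TRUE, FALSE))
  mk <- function(eff, adv, syn, a = "A1", b = "A2")
    data.frame(drug_a = a, drug_b = b, efficacy_pct = eff, adverse_pct = adv,
               synergy_pts = syn)
  # top tier: efficacy 76 / adverse 2.4 passes both tiers
  f <- filter_candidates(mk(76, 2.4, 25), meta)
  expect_equal(nrow(f$passing), 1L)
  expect_equal(nrow(f$top), 1L)
  # pass tier only: adverse 3.0 is above the strict 2.5 top bound
  f2 <- filter_candidates(mk(80, 3.0, 25), meta)
  expect_equal(nrow(f2$passing), 1L)
  expect_equal(nrow(f2$top), 0L)
  # one drug lacking a flag excludes the pair entirely
  f3 <- filter_candidates(mk(90, 1.0, 25, b = "B1"), meta)
  expect_equal(nrow(f3$passing), 0L)
  expect_false(f3$annotated$eligible)

  # deterministic total order
  sc <- rbind(mk(80, 2, 30), mk(80, 1, 25, b = "B1"), mk(90, 5, 21))
  r <- filter_candidates(sc, meta)$annotated
  expect_equal(r$efficacy_pct, c(90, 80, 80))
  expect_equal(r$adverse_pct[2:3], c(1, 2))
})

test_that("boundary semantics follow the stated wording exactly", {
  meta <- data.frame(drug = c("A1", "A2"), safe_profile = TRUE,
                     no_pain_liability = TRUE, no_known_regen_effect = TRUE,
                     crosses_bbb = TRUE)
  case <- function(eff, adv, syn)
    filter_candidates(data.frame(drug_a = "A1", drug_b = "A2",
                                 efficacy_pct = eff, adverse_pct = adv,
                                 synergy_pts = syn), meta)
  # efficacy >= 23 inclusive
  expect_true(case(23, 0, 21)$annotated$pass_tier)
  expect_false(case(22.9, 0, 21)$annotated$pass_tier)
  # adverse <= 17 inclusive
  expect_true(case(50, 17, 21)$annotated$pass_tier)
  expect_false(case(50, 17.1, 21)$annotated$pass_tier)
  # synergy > 20 strict
  expect_false(case(50, 0, 20)$annotated$pass_tier)
  expect_true(case(50, 0, 20.1)$annotated$pass_tier)
  # top tier: > 75 and < 2.5, both strict
  expect_false(case(75, 2.4, 21)$annotated$top_tier)
  expect_true(case(75.1, 2.4, 21)$annotated$top_tier)
  expect_false(case(80, 2.5, 21)$annotated$top_tier)
  expect_true(case(80, 2.49, 21)$annotated$top_tier)
})

test_that("mode-of-action extraction ranks non-additive nodes symmetrically", {
  fx <- make_screen_fixture()
  da <- drug_signature("Da", data.frame(protein = "A", action = 1),
                       all_true_flags)
  dnull <- drug_signature("Dn", data.frame(protein = character(0),
                                           action = numeric(0)),
                          all_true_flags)
  # pairing with an empty drug: every contribution is exactly zero
  moa0 <- extract_moa(fx$model, list(da, dnull), top_k = 10)
  expect_true(all(moa0$contribution == 0))
  expect_error(extract_moa(fx$model, list(da, dnull), top_k = 0), "top_k")

  # planted synthetic pair: the convergence read-outs carry the synergy
  dat <- generate_scenario_data(fast_scenario(seed = 5))
  pr <- dat$labels$planted_pairs[[1L]]
  pair <- list(dat$library[[pr[1]]], dat$library[[pr[2]]])
  moa <- extract_moa(dat$ground_truth_model, pair, dat$signatures$protection,
                     top_k = length(dat$labels$moa_nodes))
  expect_gte(length(intersect(moa$node, dat$labels$moa_nodes)),
             ceiling(length(dat$labels$moa_nodes) / 2))
  # invariant to drug order
  moa_swapped <- extract_moa(dat$ground_truth_model, rev(pair),
                             dat$signatures$protection,
                             top_k = length(dat$labels$moa_nodes))
  expect_identical(moa, moa_swapped)
})
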