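test_that("interactome generation hits the requested statistics", {
  sc <- scenario(seed = 1, n_nodes = 500, mean_degree = 13)
  net <- generate_interactome(sc)
  avg <- 2 * nrow(net$edges) / length(net$nodes)
  expect_gte(avg, 13 * 0.85)
  expect_lte(avg, 13 * 1.15)
  inh <- mean(net$edges$sign < 0)
  expect_lt(abs(inh - 0.25), 0.025)
  comp <- igraph::components(
    igraph::graph_from_data_frame(net$edges[, 1:2], vertices = net$nodes),
    mode = "weak")
  expect_gte(max(comp$csize), 0.9 * length(net$nodes))
})

test_that("generators are pure functions of the scenario", {
  sc <- scenario(seed = 7, n_nodes = 10, mean_degree = 2)
  expect_identical(generate_interactome(sc), generate_interactome(sc))
  sc2 <- fast_scenario(seed = 3)
  d1 <- generate_scenario_data(sc2)
  d2 <- generate_scenario_data(sc2)
  expect_identical(d1$interactome, d2$interactome)
  expect_identical(d1$restrictions$rows, d2$restrictions$rows)
  expect_identical(d1$labels, d2$labels)
  expect_identical(lapply(d1$library, `[[`, "targets"),
                   lapply(d2$library, `[[`, "targets"))
})

test_that("zero inhibitory fraction yields an all-activating graph", {
  sc <- scenario(seed = 2, n_nodes = 60, mean_degree = 4,
                 inhibitory_fraction = 0)
  net <- generate_interactome(sc)
  expect_true(all(net$edges$sign == 1))
  expect_error(scenario(n_nodes = 20, mean_degree = 25), "infeasible degree")
})

test_that("condition seed sets respect the requested overlap", {
  sc <- scenario(seed = 5, n_nodes = 200, mean_degree = 5, n_motives = 4,
                 seeds_per_motive = 5, seed_overlap = 0.5)
  net <- generate_interactome(sc)
  ss <- generate_condition_seeds(net, sc)
  inter <- length(intersect(unique(ss$degeneration$entries$protein),
                            unique(ss$protection$entries$protein)))
  expect_true(inter %in% 9:11)

  sc0 <- scenario(seed = 5, n_nodes = 200, mean_degree = 5, seed_overlap = 0)
  ss0 <- generate_condition_seeds(generate_interactome(sc0), sc0)
  expect_length(intersect(ss0$degeneration$entries$protein,
                          ss0$protection$entries$protein), 0L)

  sc1 <- scenario(seed = 5, n_nodes = 200, mean_degree = 5, seed_overlap = 1)
  ss1 <- generate_condition_seeds(generate_interactome(sc1), sc1)
  expect_setequal(ss1$degeneration$entries$protein,
                  ss1$protection$entries$protein)

  # impossible request: more distinct proteins than nodes
  sc_bad <- scenario(seed = 5, n_nodes = 12, mean_degree = 3, n_motives = 4,
                     seeds_per_motive = 2, seed_overlap = 0)
  expect_error(generate_condition_seeds(generate_interactome(sc_bad), sc_bad),
               "distinct seed proteins")
})

test_that("the hidden ground-truth model respects curated signs and is seeded", {
  sc <- fast_scenario(seed = 4)
  net <- generate_interactome(sc)
  m1 <- generate_ground_truth_model(net, sc)
  m2 <- generate_ground_truth_model(net, sc)
  expect_identical(m1$strengths, m2$strengths)
  expect_identical(m1$bias, m2$bias)
  inh <- m1$edges$sign < 0
  expect_true(all(m1$strengths[inh] <= 0))
  expect_true(all(m1$strengths[!inh] >= 0))
})

test_that("noiseless restrictions are exactly satisfied by their generator", {
  dat <- generate_scenario_data(fast_scenario(seed = 2))
  ev <- evaluate_restrictions(dat$ground_truth_model, dat$restrictions)
  expect_equal(ev$satisfaction, 1)
  expect_true(all(ev$row_mse < 1e-10))
  expect_length(attr(dat$restrictions, "noisy_rows"), 0L)
})

test_that("restriction noise flips roughly the requested fraction of rows", {
  sc <- scenario(seed = 9, n_nodes = 100, mean_degree = 5,
                 n_restrictions = 50, restriction_noise = 0.2)
  net <- generate_interactome(sc)
  seeds <- generate_condition_seeds(net, sc)
  map <- expand_map(net, seeds$degeneration)
  gt <- generate_ground_truth_model(net, sc, map = map)
  rt <- generate_restrictions(gt, sc, map = map)
  n_noisy <- length(attr(rt, "noisy_rows"))
  # 50 * 0.2 = 10 expected, binomial sd = sqrt(50 * .2 * .8) = 2.83
  expect_gte(n_noisy, 10 - 3 * 2.83)
  expect_lte(n_noisy, 10 + 3 * 2.83)
  expect_length(rt$rows, 50L)
  # flipped rows are exactly the rows the generator no longer satisfies
  ev <- evaluate_restrictions(gt, rt)
  strong <- names(ev$per_row)[!ev$per_row]
  expect_true(all(strong %in% attr(rt, "noisy_rows")))

  sc1 <- scenario(seed = 9, n_nodes = 100, mean_degree = 5, n_restrictions = 1)
  rt1 <- generate_restrictions(
    generate_ground_truth_model(generate_interactome(sc1), sc1), sc1)
  expect_length(rt1$rows, 1L)
})

test_that("the drug library plants the advertised roles", {
  dat <- generate_scenario_data(fast_scenario(seed = 6))
  lab <- dat$labels
  expect_length(lab$planted_pairs, 1L)
  expect_length(lab$planted_pairs[[1L]], 2L)
  expect_length(dat$library, 12L)

  # planted pair: one branch regulator each, all flags true
  pr <- lab$planted_pairs[[1L]]
  expect_setequal(c(dat$library[[pr[1]]]$targets$protein,
                    dat$library[[pr[2]]]$targets$protein), lab$branch)
  expect_true(all(dat$library[[pr[1]]]$eligibility))

  # decoy pair fails on exactly one flag
  decoy_flags <- c(dat$library[[lab$decoy_pair[1]]]$eligibility,
                   dat$library[[lab$decoy_pair[2]]]$eligibility)
  expect_equal(sum(!decoy_flags), 1L)

  # generation-time verification: pair beats singles by the margin
  expect_gte(lab$planted_synergy_pts, 18)
  expect_lte(max(lab$planted_single_efficacy), 62)

  # null drugs hit bottom-quartile influence nodes
  infl <- node_influence(dat$ground_truth_model)
  pool <- setdiff(dat$map_degeneration$nodes, c(lab$readout, lab$branch))
  cutoff <- stats::quantile(infl[pool], 0.25)
  null_targets <- unique(unlist(lapply(dat$library[lab$null_drugs],
                                       function(d) d$targets$protein)))
  expect_true(all(infl[null_targets] <= cutoff + 1e-9))
})

test_that("scenario data writes all tables and they re-read consistently", {
  outdir <- file.path(tempdir(), "synthout")
  unlink(outdir, recursive = TRUE)
  dat <- generate_scenario_data(fast_scenario(seed = 8), outdir = outdir)
  expect_true(all(file.exists(file.path(outdir,
    c("interactome.tsv", "seeds.tsv", "restrictions.tsv", "drug_targets.tsv",
      "drug_metadata.tsv", "signatures.tsv", "ground_truth.yaml")))))
  net <- read_interactome(file.path(outdir, "interactome.tsv"))
  expect_equal(nrow(net$edges), nrow(dat$interactome$edges))
  rt <- read_restrictions(file.path(outdir, "restrictions.tsv"))
  expect_equal(length(rt$rows), length(dat$restrictions$rows))
  lib <- read_drug_library(file.path(outdir, "drug_targets.tsv"),
                           file.path(outdir, "drug_metadata.tsv"))
  expect_identical(lapply(lib, `[[`, "targets"),
                   lapply(dat$library[names(lib)], `[[`, "targets"))
  gt <- yaml::read_yaml(file.path(outdir, "ground_truth.yaml"))
  expect_identical(unlist(gt$planted_pairs), dat$labels$planted_pairs[[1L]])
})
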