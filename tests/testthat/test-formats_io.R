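test_that("interactome edge tables load, merge duplicates, and reject conflicts", {
  p <- write_lines_tmp(c("source\ttarget\tsign\tweight",
                         "A\tB\t+\t0.9", "B\tC\t-\t0.5", "A\tC\t+1\t1"))
  net <- read_interactome(p)
  expect_s3_class(net, "interactome")
  expect_equal(length(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(net$edges$sign[net$edges$source == "B"], -1)

  # duplicate rows with equal sign merge by max weight
  p2 <- write_lines_tmp(c("source\ttarget\tsign\tweight",
                          "A\tB\t+\t0.4", "A\tB\t+1\t0.7"))
  expect_message(net2 <- read_interactome(p2), "merged 1 duplicate")
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$weight, 0.7)

  # opposite signs on the same pair fail loudly
  p3 <- write_lines_tmp(c("source\ttarget\tsign\tweight",
                          "A\tB\t+\t0.4", "A\tB\t-\t0.7"))
  expect_error(read_interactome(p3), "conflicting signs")

  # self-loops are dropped and reported
  p4 <- write_lines_tmp(c("source\ttarget\tsign\tweight",
                          "A\tA\t+\t0.4", "A\tB\t+\t0.7"))
  expect_message(net4 <- read_interactome(p4), "self-loop")
  expect_equal(nrow(net4$edges), 1L)
})

test_that("malformed interactome rows raise errors naming the line", {
  p <- write_lines_tmp(c("source\ttarget\tsign\tweight",
                         "# a comment", "A\tB\t+\t0.9", "B\tC\t0.5"))
  expect_error(read_interactome(p), "line 4")
  p2 <- write_lines_tmp(c("source\ttarget\tsign\tweight", "A\tB\tup\t0.9"))
  expect_error(read_interactome(p2), "unknown sign token 'up'")
  p3 <- write_lines_tmp(c("source\ttarget\tsign\tweight", "A\tB\t+\theavy"))
  expect_error(read_interactome(p3), "non-numeric weight")
})

test_that("an empty edge file yields an empty interactome without error", {
  p <- write_lines_tmp(c("source\ttarget\tsign\tweight"))
  net <- read_interactome(p)
  expect_equal(length(net$nodes), 0L)
  expect_equal(nrow(net$edges), 0L)
  p2 <- write_lines_tmp(character(0))
  expect_equal(length(read_interactome(p2)$nodes), 0L)
})

test_that("sif dialect maps relations through the lexicon", {
  p <- write_lines_tmp(c("source\trelation\ttarget",
                         "A\tactivates\tB", "B\tinhibits\tC"))
  net <- read_interactome(p, dialect = "sif",
                          sign_lexicon = c(activates = 1, inhibits = -1))
  expect_equal(sort(net$edges$sign), c(-1, 1))
  expect_true(all(net$edges$weight == 1))
  expect_error(read_interactome(p, dialect = "sif",
                                sign_lexicon = c(activates = 1)),
               "not in sign lexicon")
})

test_that("seed sets load per condition with multi-motive membership", {
  p <- write_lines_tmp(c("condition\tprotein\tmotive\texpected_state",
                         "deg\tP1\tapoptosis\t+1", "deg\tP2\tapoptosis\t-1",
                         "deg\tP3\tinflammation\t+1",
                         "deg\tP4\tinflammation\t-1"))
  ss <- read_seed_sets(p)
  expect_named(ss, "deg")
  expect_equal(nrow(ss$deg$entries), 4L)

  # the same protein may belong to two motives; both entries are retained
  p2 <- write_lines_tmp(c("condition\tprotein\tmotive\texpected_state",
                          "deg\tP1\tapoptosis\t+1",
                          "deg\tP1\tinflammation\t+1"))
  expect_equal(nrow(read_seed_sets(p2)$deg$entries), 2L)

  # ... but at most once per motive
  p3 <- write_lines_tmp(c("condition\tprotein\tmotive\texpected_state",
                          "deg\tP1\tapoptosis\t+1", "deg\tP1\tapoptosis\t-1"))
  expect_error(read_seed_sets(p3), "twice in the same motive")

  p4 <- write_lines_tmp(c("condition\tprotein\tmotive\texpected_state",
                          "deg\tP1\t\t+1"))
  expect_error(read_seed_sets(p4), "blank motive")
})

test_that("drug libraries require explicit eligibility and valid actions", {
  tp <- write_lines_tmp(c("drug\ttarget\taction",
                          "D1\tP1\t+", "D1\tP2\t-", "D2\tP3\t+1", "D2\tP4\t-1"))
  mp <- write_lines_tmp(c(paste("drug", "safe_profile", "no_pain_liability",
                                "no_known_regen_effect", "crosses_bbb",
                                sep = "\t"),
                          "D1\tTRUE\tTRUE\tTRUE\tTRUE",
                          "D2\tTRUE\tFALSE\tTRUE\tTRUE",
                          "D3\tTRUE\tTRUE\tTRUE\tFALSE"))
  lib <- read_drug_library(tp, mp)
  expect_length(lib, 3L)
  expect_equal(nrow(lib$D1$targets), 2L)
  # a drug with only a metadata row is a legal null drug
  expect_equal(nrow(lib$D3$targets), 0L)
  expect_false(lib$D2$eligibility[["no_pain_liability"]])

  mp_missing <- write_lines_tmp(c(paste("drug", "safe_profile",
                                        "no_pain_liability",
                                        "no_known_regen_effect", "crosses_bbb",
                                        sep = "\t"),
                                  "D1\tTRUE\tTRUE\tTRUE\tTRUE"))
  expect_error(read_drug_library(tp, mp_missing), "no metadata row")

  mp_na <- write_lines_tmp(c(paste("drug", "safe_profile", "no_pain_liability",
                                   "no_known_regen_effect", "crosses_bbb",
                                   sep = "\t"),
                             "D1\tTRUE\t\tTRUE\tTRUE",
                             "D2\tTRUE\tTRUE\tTRUE\tTRUE"))
  expect_error(read_drug_library(tp, mp_na), "malformed|invalid")

  tp_bad <- write_lines_tmp(c("drug\ttarget\taction", "D1\tP1\tagonist"))
  expect_error(read_drug_library(tp_bad, mp), "unknown sign token")
})

test_that("restriction tables round-trip through the long format", {
  rt <- restriction_table(list(
    list(row_id = "r1", input = c(P1 = 1, P2 = -1),
         output = c(P3 = 0.25, P4 = -0.75), tolerance = 0.5),
    list(row_id = "r2", input = c(P1 = -1),
         output = c(P3 = -0.1), tolerance = 0.3)))
  p <- tempfile(fileext = ".tsv")
  write_restrictions(rt, p)
  back <- read_restrictions(p)
  expect_equal(back$rows, rt$rows)

  bad <- write_lines_tmp(c("row_id\tside\tprotein\tvalue\ttolerance",
                           "r1\tin\tP1\t1\t0.5", "r1\tout\tP2\t0.5\t0.4"))
  expect_error(read_restrictions(bad), "inconsistent tolerances")
  bad2 <- write_lines_tmp(c("row_id\tside\tprotein\tvalue\ttolerance",
                            "r1\tboth\tP1\t1\t0.5"))
  expect_error(read_restrictions(bad2), "side must be")
})

test_that("loading is insensitive to input row order", {
  lines <- c("source\ttarget\tsign\tweight",
             "A\tB\t+\t0.9", "B\tC\t-\t0.5", "A\tC\t+\t1")
  net1 <- read_interactome(write_lines_tmp(lines))
  net2 <- read_interactome(write_lines_tmp(lines[c(1, 4, 2, 3)]))
  expect_identical(net1, net2)

  sl <- c("condition\tprotein\tmotive\texpected_state",
          "deg\tP1\tm1\t+1", "deg\tP2\tm2\t-1", "pro\tP3\tm1\t+1")
  expect_identical(read_seed_sets(write_lines_tmp(sl)),
                   read_seed_sets(write_lines_tmp(sl[c(1, 3, 4, 2)])))
})

test_that("ranked combination tables write deterministically and round-trip", {
  scores <- data.frame(drug_a = c("D2", "D1", "D1"),
                       drug_b = c("D3", "D3", "D2"),
                       efficacy_pct = c(80.123456, 91.5, 91.5),
                       adverse_pct = c(1.25, 3.5, 2.5),
                       synergy_pts = c(25.1, 30.2, -4.5),
                       eligible = c(TRUE, TRUE, FALSE),
                       pass_tier = c(TRUE, TRUE, FALSE),
                       top_tier = c(TRUE, FALSE, FALSE))
  p <- tempfile(fileext = ".tsv")
  write_ranked_combinations(scores, p)
  back <- read_ranked_combinations(p)
  # ranking rule: efficacy desc, adverse asc, synergy desc, canonical ids
  expect_equal(back$drug_a, c("D1", "D1", "D2"))
  expect_equal(back$adverse_pct[1:2], c(2.5, 3.5))
  expect_equal(back$efficacy_pct[3], 80.123456, tolerance = 1e-6)
  # writing what was read back reproduces the file byte for byte
  p2 <- tempfile(fileext = ".tsv")
  write_ranked_combinations(back, p2)
  expect_identical(readLines(p), readLines(p2))

  empty <- scores[0, ]
  p3 <- tempfile(fileext = ".tsv")
  write_ranked_combinations(empty, p3)
  expect_length(readLines(p3), 1L)
  expect_equal(nrow(read_ranked_combinations(p3)), 0L)
})

test_that("model checkpoints reload bit-exactly", {
  model <- random_dag_model(8, seed = 42)
  fit <- propagate(model, c(N01 = 0.5))
  p <- tempfile(fileext = ".tsv")
  write_model_checkpoint(model, p)
  back <- read_model_checkpoint(p)
  expect_identical(back$strengths[order(paste(back$edges$source,
                                              back$edges$target))],
                   model$strengths[order(paste(model$edges$source,
                                               model$edges$target))])
  expect_identical(sort(back$nodes), sort(model$nodes))
  expect_equal(back$alpha, model$alpha)
  expect_equal(back$eps, model$eps)
  refit <- propagate(back, c(N01 = 0.5))
  expect_identical(refit$state[names(fit$state)], fit$state)
})
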