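test_that("trial simulation is deterministic per seed and respects the screen", {
  spec <- two_category_config()$categories[[1]]
  r1 <- simulate_trial(spec, seed = 42, study_id = "t")
  r2 <- simulate_trial(spec, seed = 42, study_id = "t")
  expect_identical(r1, r2)
  expect_false(identical(r1, simulate_trial(spec, seed = 43, study_id = "t")))

  # screened trials are Fisher-significant by construction, and eligible
  for (i in 1:25) {
    r <- simulate_trial(spec, seed = i, study_id = "t")
    expect_lt(fisher_exact_two_sided(
      c(r$events_a, r$n_a - r$events_a, r$events_b, r$n_b - r$events_b)), 0.05)
    expect_true(validate_trial(r)$eligible)
    expect_gte(r$n_redraws, 0L)
    expect_lte(r$lost_to_followup, r$n_a + r$n_b)
  }
})

test_that("corpus simulation is reproducible and category-stable", {
  cfg <- two_category_config(seed = 7, n_studies = 4)
  c1 <- simulate_corpus(cfg)
  c2 <- simulate_corpus(cfg)
  expect_identical(c1, c2)
  expect_identical(nrow(c1), 8L)
  expect_identical(as.vector(table(c1$treatment_category)[
    c("neoadjuvant immunotherapy", "surgical intervention")]), c(4L, 4L))

  # byte-identical CSV under the same seed
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_corpus(c1, f1); write_corpus(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(simulate_corpus(cfg2), c1))

  # substreams are keyed by category name: dropping one category leaves the
  # other category's trials untouched
  solo <- simulation_config(categories = cfg$categories[2], seed = 7L)
  expect_identical(simulate_corpus(solo),
                   c1[c1$treatment_category == "surgical intervention", ])
})

test_that("configuration validation rejects impossible setups", {
  spec <- two_category_config()$categories[[1]]
  expect_error(simulation_config(list(spec, spec)), "duplicate category")
  expect_error(category_spec("surgical intervention", n_studies = 0,
                             arm_size_range = c(10, 20),
                             control_event_rate_range = c(0.2, 0.4),
                             odds_ratio_range = c(2, 3)),
               "positive integer")
  expect_error(category_spec("made up category", 3, c(10, 20), c(0.2, 0.4),
                             c(2, 3)), "unknown treatment_category")
  expect_error(category_spec("surgical intervention", 3, c(20, 10), c(0.2, 0.4),
                             c(2, 3)), "ordered pair")
})

test_that("an exhausted significance screen fails loudly", {
  null_spec <- category_spec(
    "follow-up and chemoprevention", n_studies = 1,
    arm_size_range = c(8, 10), control_event_rate_range = c(0.45, 0.55),
    odds_ratio_range = c(1, 1), significance_screen = TRUE
  )
  expect_error(
    simulate_trial(null_spec, seed = 5, max_resamples = 3),
    "increase the configured odds ratio"
  )
})

test_that("a null odds ratio without screening keeps the exact test conservative", {
  null_spec <- category_spec(
    "follow-up and chemoprevention", n_studies = 1,
    arm_size_range = c(15, 60), control_event_rate_range = c(0.2, 0.5),
    odds_ratio_range = c(1, 1), significance_screen = FALSE
  )
  n_draws <- 10000L
  run_null <- function(seed_off) {
    draws <- vapply(seq_len(n_draws), function(i) {
      r <- simulate_trial(null_spec, seed = i + seed_off, study_id = "t")
      c(rate_diff = r$events_a / r$n_a - r$events_b / r$n_b,
        sig = as.numeric(r$reported_p < 0.05))
    }, numeric(2))
    draws
  }
  draws <- run_null(100000L)
  # empirical type-I proportion at most 0.05 plus 3 binomial standard errors
  expect_lte(mean(draws["sig", ]), 0.05 + 3 * sqrt(0.05 * 0.95 / n_draws))
  # null effect: mean event-rate difference within 3 standard errors of 0
  rd <- draws["rate_diff", ]
  expect_lt(abs(mean(rd)), 3 * stats::sd(rd) / sqrt(n_draws))
})

test_that("the shipped default configuration has the documented structure", {
  cfg <- nccn_like_config()
  expect_s3_class(cfg, "simulation_config")
  expect_identical(length(cfg$categories), 9L)
  counts <- vapply(cfg$categories, `[[`, integer(1), "n_studies")
  expect_identical(sum(counts), 67L)
  nms <- vapply(cfg$categories, `[[`, character(1), "treatment_category")
  expect_setequal(nms, treatment_categories())
  expect_identical(nccn_like_config(seed = 99)$seed, 99L)
  # missing-field diagnostics for hand-written configs
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("alpha: 0.05", f)
  expect_error(read_sim_config(f), "missing field 'categories'")
})

test_that("recovery experiment reports one summary per replicate and a near-symmetric null", {
  cfg <- two_category_config(seed = 3, n_studies = 4)
  rep1 <- recovery_experiment(cfg, n_reps = 1, seed = 5)
  expect_length(rep1$summaries, 1L)
  expect_s3_class(rep1$summaries[[1]], "corpus_summary")
  expect_identical(nrow(rep1$median_of_medians), 2L)

  # two categories sharing all generative parameters: median-FI differences
  # centred at zero
  spec <- cfg$categories[[2]]
  twin <- spec; twin$treatment_category <- "adjuvant chemotherapy"
  twin_cfg <- simulation_config(list(spec, twin), seed = 3L)
  rep2 <- recovery_experiment(twin_cfg, n_reps = 30, seed = 11)
  m <- rep2$medians
  d <- m$median_fi[m$treatment_category == "surgical intervention"] -
    m$median_fi[m$treatment_category == "adjuvant chemotherapy"]
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)) + 1e-9)
  expect_error(rank_recovery_proportion(rep2, "nope", "surgical intervention"),
               "not present")
})
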