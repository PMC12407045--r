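test_that("quantile triplet follows the linear-interpolation rule", {
  expect_equal(quantile_triplet(c(1, 2, 3, 4, 5)),
               c(q1 = 2, median = 3, q3 = 4))
  expect_equal(quantile_triplet(7), c(q1 = 7, median = 7, q3 = 7))
  expect_equal(quantile_triplet(c(0, 22, 11, 12))[["median"]], 11.5)
  expect_error(quantile_triplet(numeric(0)), "empty")
  expect_error(quantile_triplet(c(1, NA)), "NA")

  set.seed(5150)
  for (i in 1:100) {
    x <- sample(0:60, sample(1:40, 1), replace = TRUE)
    q <- quantile_triplet(x)
    expect_equal(unname(q), oracle_quantile(x, c(0.25, 0.5, 0.75)))
    expect_true(q[["q1"]] <= q[["median"]] && q[["median"]] <= q[["q3"]])
  }
})

test_that("per-study scoring combines FI with the LTFU comparison", {
  corpus <- dplyr::bind_rows(
    trial_record(study_id = "balanced", publication_year = 2010,
                 treatment_category = "surgical intervention",
                 events_a = 5, n_a = 10, events_b = 5, n_b = 10,
                 lost_to_followup = 0),
    trial_record(study_id = "fragile-ltfu", publication_year = 2011,
                 treatment_category = "surgical intervention",
                 events_a = 1, n_a = 10, events_b = 9, n_b = 10,
                 lost_to_followup = 5),
    trial_record(study_id = "fragile-boundary", publication_year = 2012,
                 treatment_category = "surgical intervention",
                 events_a = 1, n_a = 10, events_b = 9, n_b = 10,
                 lost_to_followup = 3)
  )
  scored <- score_corpus(corpus)
  expect_identical(scored$fi, c(0L, 3L, 3L))
  # strictly-greater rule: 5 > 3 flags, 3 > 3 does not
  expect_identical(scored$ltfu_exceeds_fi, c(FALSE, TRUE, FALSE))
  expect_identical(scored$ltfu_exceeds_fi,
                   scored$lost_to_followup > scored$fi)

  bad <- corpus; bad$reported_significant[2] <- FALSE
  expect_error(score_corpus(bad), "fragile-ltfu.*not_significant")
  expect_error(score_corpus(corpus[0, ]), "empty")
})

test_that("corpus summary flags categories where median LTFU exceeds median FI", {
  mk <- function(id, cat, fi_table, ltfu) {
    trial_record(study_id = id, publication_year = 2010,
                 treatment_category = cat,
                 events_a = fi_table[1], n_a = fi_table[1] + fi_table[2],
                 events_b = fi_table[3], n_b = fi_table[3] + fi_table[4],
                 lost_to_followup = ltfu)
  }
  # robust category: one trial, FI 3, LTFU 1 -> not flagged
  # fragile category: three trials with FI 0,0,3 and LTFU 5 -> flagged
  corpus <- dplyr::bind_rows(
    mk("s1", "surgical intervention", c(1, 9, 9, 1), 1),
    mk("f1", "neoadjuvant immunotherapy", c(5, 5, 5, 5), 5),
    mk("f2", "neoadjuvant immunotherapy", c(4, 6, 6, 4), 5),
    mk("f3", "neoadjuvant immunotherapy", c(1, 9, 9, 1), 5)
  )
  scored <- score_corpus(corpus)
  smry <- summarize_corpus(scored, corpus)
  expect_identical(smry$flagged_categories, "neoadjuvant immunotherapy")
  pc <- smry$per_category
  expect_identical(sum(pc$n_studies), nrow(corpus))
  # only categories with studies appear
  expect_identical(nrow(pc), 2L)
  expect_true(all(pc$fi_q1 <= pc$median_fi & pc$median_fi <= pc$fi_q3))
  expect_true(all(pc$ltfu_q1 <= pc$median_ltfu & pc$median_ltfu <= pc$ltfu_q3))
  expect_error(summarize_corpus(scored[0, ], corpus), "empty")

  # permutation invariance in study order
  perm <- sample(nrow(corpus))
  smry2 <- summarize_corpus(scored[perm, ], corpus)
  expect_equal(smry2$per_category, smry$per_category)
  expect_equal(smry2$overall, smry$overall)

  # adding a study at the category median leaves the median unchanged
  med <- pc$median_fi[pc$treatment_category == "neoadjuvant immunotherapy"]
  extra <- mk("f4", "neoadjuvant immunotherapy", c(5, 5, 5, 5), 5) # fi 0 = med
  expect_identical(med, 0)
  corpus3 <- dplyr::bind_rows(corpus, extra)
  smry3 <- summarize_corpus(score_corpus(corpus3), corpus3)
  expect_identical(
    smry3$per_category$median_fi[
      smry3$per_category$treatment_category == "neoadjuvant immunotherapy"],
    med)
})

test_that("summary tables round-trip through CSV", {
  corpus <- fixture_corpus()
  scored <- score_corpus(corpus)
  smry <- summarize_corpus(scored, corpus)
  dir <- withr::local_tempdir()
  paths <- render_summary_tables(smry, dir)
  expect_true(all(file.exists(paths)))
  percat <- readr::read_csv(paths[["per_category"]], show_col_types = FALSE)
  expect_identical(nrow(percat), nrow(smry$per_category))
  expect_equal(percat$median_fi, smry$per_category$median_fi)
  expect_identical(percat$flagged, smry$per_category$flagged)
  overall <- readr::read_csv(paths[["overall"]], show_col_types = FALSE)
  expect_equal(overall$median_fi, smry$overall$median_fi)

  p1 <- plot_fi_by_category(smry)
  p2 <- plot_fi_vs_ltfu(smry)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
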