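test_that("the (1,9,9,1) worked example: FI 3 with the frozen p trajectory", {
  res <- fragility_index(contingency_table(1, 9, 9, 1))
  expect_identical(res$fi, 3L)
  expect_equal(res$p_initial, 202 / 184756, tolerance = 1e-12)
  expect_identical(res$modified_arm, "A") # arm A holds the fewer events
  expect_length(res$trajectory, 3L)
  # frozen from step-wise exhaustive enumeration (oracle_fisher_p)
  traj_p <- vapply(res$trajectory, `[[`, numeric(1), "p")
  expect_equal(traj_p, c(0.005477495, 0.01976661, 0.05727554), tolerance = 1e-6)
  expect_equal(traj_p,
               c(oracle_fisher_p(2, 8, 9, 1), oracle_fisher_p(3, 7, 9, 1),
                 oracle_fisher_p(4, 6, 9, 1)), tolerance = 1e-12)
  expect_identical(unname(res$trajectory[[3]]$table), c(4L, 6L, 9L, 1L))
  expect_identical(res$p_final, traj_p[3])
})

test_that("non-significant tables have FI 0 and an empty trajectory", {
  res <- fragility_index(contingency_table(5, 5, 5, 5))
  expect_identical(res$fi, 0L)
  expect_identical(res$p_initial, res$p_final)
  expect_true(is.na(res$modified_arm))
  expect_length(res$trajectory, 0L)
  # the same table is 'significant' only relative to alpha: at alpha below
  # its p the search never starts
  expect_identical(fragility_index(contingency_table(1, 9, 9, 1),
                                   alpha = 0.001)$fi, 0L)
  expect_error(fragility_index(contingency_table(1, 9, 9, 1), alpha = 1.2),
               "between 0 and 1")
})

test_that("brute-force oracle worked examples", {
  expect_identical(fragility_index_bruteforce(c(5, 5, 5, 5), max_mods = 10), 0L)
  expect_identical(fragility_index_bruteforce(c(1, 9, 9, 1), max_mods = 9), 3L)
  # at a vanishing alpha the table is already non-significant: k = 0, in
  # line with the FI-zero convention
  expect_identical(fragility_index_bruteforce(c(1, 9, 9, 1), alpha = 1e-9,
                                              max_mods = 9), 0L)
  # a deeply significant table at a vanishing alpha cannot lose
  # significance within the bound: "not found"
  expect_lt(fisher_exact_two_sided(c(0, 20, 20, 0)), 1e-9)
  expect_true(is.na(fragility_index_bruteforce(c(0, 20, 20, 0), alpha = 1e-9,
                                               max_mods = 1)))
  expect_identical(fragility_index_bruteforce(c(0, 20, 20, 0), alpha = 1e-9,
                                              max_mods = 5), 2L)
  # single-arm searches: through arm A three conversions suffice; through
  # arm B the supply of non-events runs out while still significant
  expect_identical(fragility_index_bruteforce(c(1, 9, 9, 1), arms = "A"), 3L)
  expect_true(is.na(fragility_index_bruteforce(c(1, 9, 9, 1), arms = "B")))
})

test_that("saturation of the modified arm is signalled with the partial trajectory", {
  # (2,0,2,13) is significant but arm A (tied events, chosen on the tie)
  # has no non-events to convert
  expect_lt(fisher_exact_two_sided(c(2, 0, 2, 13)), 0.05)
  err <- tryCatch(fragility_index(c(2, 0, 2, 13)),
                  fragility_saturation_error = function(e) e)
  expect_s3_class(err, "fragility_saturation_error")
  expect_identical(err$arm, "A")
  expect_length(err$trajectory, 0L)
  # the exhaustive oracle still finds a one-step solution through arm B
  expect_identical(fragility_index_bruteforce(c(2, 0, 2, 13), max_mods = 13), 1L)
})

test_that("FI is 0 exactly when the initial p reaches alpha (random small tables)", {
  set.seed(2040)
  for (i in 1:300) {
    tab <- random_table(20)
    p <- fisher_exact_two_sided(tab)
    res <- tryCatch(fragility_index(tab),
                    fragility_saturation_error = function(e) e)
    if (inherits(res, "fragility_saturation_error")) {
      expect_lt(p, 0.05) # saturation can only happen mid-search
      next
    }
    expect_identical(res$fi == 0L, p >= 0.05)
    if (res$fi > 0L) {
      # threshold coherence: significance is lost at step fi and not before
      expect_gte(res$p_final, 0.05)
      p_prev <- if (res$fi > 1L) res$trajectory[[res$fi - 1L]]$p else res$p_initial
      expect_lt(p_prev, 0.05)
      expect_length(res$trajectory, res$fi)
      # and the sequential count matches the same-arm exhaustive minimum
      expect_identical(res$fi,
                       fragility_index_bruteforce(tab, max_mods = 50,
                                                  arms = res$modified_arm))
    }
  }
})
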