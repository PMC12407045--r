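# Independent oracles and fixture builders shared across the suite.

# Two-sided Fisher p by direct enumeration with binomial coefficients --
# deliberately a different computational path from the package's
# dhyper-based implementation.
oracle_fisher_p <- function(a, b, c, d, tie_tol = 1e-7) {
  nA <- a + b; nB <- c + d; K <- a + c; N <- nA + nB
  xs <- max(0, K - nB):min(K, nA)
  if (length(xs) == 1L) return(1)
  pr <- choose(nA, xs) * choose(nB, K - xs) / choose(N, K)
  obs <- pr[xs == a]
  min(1, sum(pr[pr <= obs * (1 + tie_tol)]))
}

# Hand-rolled linear-interpolation quantiles (h = (n-1)p + 1 on the sorted
# sample), independent of stats::quantile.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(x[n])
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }, numeric(1))
}

# Random valid 2x2 table with arm totals up to max_n.
random_table <- function(max_n = 30L) {
  nA <- sample(max_n, 1)
  nB <- sample(max_n, 1)
  a <- sample(0:nA, 1)
  c <- sample(0:nB, 1)
  c(a, nA - a, c, nB - c)
}

# Three-trial fixture corpus: two eligible trials plus whatever extra rows
# the caller appends.
fixture_corpus <- function() {
  dplyr::bind_rows(
    trial_record(
      study_id = "trial-01", short_name = "ALPHA", publication_year = 2015,
      treatment_category = "surgical intervention",
      events_a = 1, n_a = 10, events_b = 9, n_b = 10,
      lost_to_followup = 5, reported_significant = TRUE, reported_p = 0.001
    ),
    trial_record(
      study_id = "trial-02", short_name = "NR", publication_year = 2019,
      treatment_category = "neoadjuvant immunotherapy",
      events_a = 0, n_a = 12, events_b = 7, n_b = 12,
      lost_to_followup = 2, reported_significant = TRUE
    ),
    trial_record(
      study_id = "trial-03", short_name = "NR", publication_year = 2010,
      treatment_category = "adjuvant chemotherapy",
      events_a = 20, n_a = 100, events_b = 40, n_b = 100,
      lost_to_followup = 0, reported_significant = TRUE, reported_p = 0.003
    )
  )
}

# Small two-category configuration: one deliberately underpowered (fragile)
# category against one large, strongly powered (robust) category.
two_category_config <- function(seed = 1L, n_studies = 5L) {
  simulation_config(
    categories = list(
      category_spec(
        "neoadjuvant immunotherapy", n_studies = n_studies,
        arm_size_range = c(18, 45),
        control_event_rate_range = c(0.2, 0.4),
        odds_ratio_range = c(1.2, 2.2),
        ltfu_rate_range = c(0.05, 0.12),
        significance_screen = TRUE
      ),
      category_spec(
        "surgical intervention", n_studies = n_studies,
        arm_size_range = c(90, 270),
        control_event_rate_range = c(0.2, 0.4),
        odds_ratio_range = c(2.2, 3.5),
        ltfu_rate_range = c(0.01, 0.04),
        significance_screen = TRUE
      )
    ),
    seed = seed
  )
}
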