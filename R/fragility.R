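# The Fragility Index: iterative event-flipping until significance is lost.

new_fragility_result <- function(fi, p_initial, p_final, modified_arm,
                                 trajectory, alpha) {
  structure(
    list(
      fi = as.integer(fi),
      p_initial = p_initial,
      p_final = p_final,
      modified_arm = modified_arm,
      trajectory = trajectory,
      alpha = alpha
    ),
    class = "fragility_result"
  )
}

#' @export
print.fragility_result <- function(x, ...) {
  cat("Fragility Index:", x$fi, "\n")
  cat(sprintf("  initial p = %.6g (alpha = %g)\n", x$p_initial, x$alpha))
  if (x$fi == 0L) {
    cat("  table is non-significant as given; no modification required\n")
  } else {
    cat(sprintf("  final p   = %.6g after %d non-event -> event conversion(s) in arm %s\n",
                x$p_final, x$fi, x$modified_arm))
    for (i in seq_along(x$trajectory)) {
      step <- x$trajectory[[i]]
      cat(sprintf("  step %d: (%d,%d,%d,%d)  p = %.6g\n", i,
                  step$table[[1]], step$table[[2]], step$table[[3]],
                  step$table[[4]], step$p))
    }
  }
  invisible(x)
}

fragility_saturation_error <- function(arm, trajectory, call = NULL) {
  structure(
    class = c("fragility_saturation_error", "error", "condition"),
    list(
      message = sprintf(
        "arm %s ran out of non-events after %d modification(s) before significance was lost",
        arm, length(trajectory)),
      call = call,
      arm = arm,
      trajectory = trajectory
    )
  )
}

#' Fragility Index of a significant 2x2 trial result
#'
#' The Fragility Index (FI) is the minimum number of patients whose outcome
#' status must change from non-event to event for a statistically significant
#' dichotomous trial result to lose significance under the two-sided Fisher
#' exact test. A small FI marks a fragile finding: a handful of different
#' outcomes would have erased the result.
#'
#' @param table A [contingency_table()] or numeric vector of length 4.
#' @param alpha Significance threshold; significance is lost when the exact
#'   p-value first reaches `p >= alpha`. Default 0.05.
#'
#' @return A `fragility_result` with elements:
#'   * `fi` — the index (non-negative integer);
#'   * `p_initial` — exact two-sided p of the input table;
#'   * `p_final` — p after `fi` modifications (equals `p_initial` when
#'     `fi = 0`);
#'   * `modified_arm` — `"A"` or `"B"`, or `NA` when `fi = 0`;
#'   * `trajectory` — list of `fi` steps, each a list `(table, p)` giving the
#'     modified table and its p-value;
#'   * `alpha` — the threshold used.
#'
#' @details One non-event is converted to an event per step, always in the arm
#'   with the fewer events (arm A on a tie) — the convention of the original
#'   Walsh procedure and of the widely used online calculators, which makes
#'   the index deterministic. Events are only ever added, never removed.
#'
#'   A table whose exact p-value is already `>= alpha` has `fi = 0` by
#'   convention; trials admitted to an audit on *reported* significance can
#'   legitimately come out non-significant when their counts are re-tested
#'   exactly, and FI 0 is how that shows up.
#'
#'   If the modified arm exhausts its non-events before significance is lost
#'   (impossible at `alpha = 0.05`, but reachable for tiny thresholds) a
#'   condition of class `fragility_saturation_error` is signalled, carrying
#'   the partial trajectory.
#'
#' @seealso [fragility_index_bruteforce()] for the exhaustive verification
#'   oracle, [fisher_exact_two_sided()] for the underlying test.
#'
#' @examples
#' fragility_index(contingency_table(1, 9, 9, 1)) # fi = 3
#' fragility_index(contingency_table(5, 5, 5, 5)) # fi = 0
#' @export
fragility_index <- function(table, alpha = 0.05) {
  t <- as_contingency_table(table)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number strictly between 0 and 1", call. = FALSE)
  }
  a <- t[[1]]; b <- t[[2]]; c <- t[[3]]; d <- t[[4]]
  p0 <- p2x2(a, b, c, d)
  if (p0 >= alpha) {
    return(new_fragility_result(0L, p0, p0, NA_character_, list(), alpha))
  }
  arm <- if (a <= c) "A" else "B"
  trajectory <- list()
  p <- p0
  repeat {
    if (arm == "A") {
      if (b == 0L) stop(fragility_saturation_error(arm, trajectory))
      a <- a + 1L; b <- b - 1L
    } else {
      if (d == 0L) stop(fragility_saturation_error(arm, trajectory))
      c <- c + 1L; d <- d - 1L
    }
    p <- p2x2(a, b, c, d)
    trajectory[[length(trajectory) + 1L]] <-
      list(table = c(events_a = a, nonevents_a = b,
                     events_b = c, nonevents_b = d), p = p)
    if (p >= alpha) break
  }
  new_fragility_result(length(trajectory), p0, p, arm, trajectory, alpha)
}

# Minimal k <= max_mods such that converting exactly k non-events to events in
# the given arm yields p >= alpha; NA when the bound (or the arm's supply of
# non-events) is exhausted first.
bf_arm <- function(a, b, c, d, alpha, max_mods, arm) {
  supply <- if (arm == "A") b else d
  for (k in 0:min(max_mods, supply)) {
    p <- if (arm == "A") p2x2(a + k, b - k, c, d) else p2x2(a, b, c + k, d - k)
    if (p >= alpha) return(k)
  }
  NA_integer_
}

#' Brute-force Fragility Index oracle
#'
#' Exhaustively searches for the smallest number of non-event-to-event
#' conversions, applied within a single arm (each arm tried independently),
#' that lifts the two-sided exact p-value to `>= alpha`. Used to verify
#' [fragility_index()], whose fewer-events-arm rule it does not assume.
#'
#' @inheritParams fragility_index
#' @param max_mods Upper bound on the number of conversions tried per arm.
#' @param arms Which arms to search: `"both"` (default, minimum over the two),
#'   `"A"`, or `"B"`.
#'
#' @return The minimal number of conversions as an integer, or `NA_integer_`
#'   when no solution exists within `max_mods` ("not found within bound").
#'
#' @examples
#' fragility_index_bruteforce(contingency_table(1, 9, 9, 1), max_mods = 9) # 3
#' fragility_index_bruteforce(contingency_table(1, 9, 9, 1), alpha = 1e-9,
#'                            max_mods = 9) # NA: unattainable threshold
#' @export
fragility_index_bruteforce <- function(table, alpha = 0.05, max_mods = 100L,
                                       arms = c("both", "A", "B")) {
  t <- as_contingency_table(table)
  arms <- match.arg(arms)
  a <- t[[1]]; b <- t[[2]]; c <- t[[3]]; d <- t[[4]]
  ks <- c(
    if (arms %in% c("both", "A")) bf_arm(a, b, c, d, alpha, max_mods, "A"),
    if (arms %in% c("both", "B")) bf_arm(a, b, c, d, alpha, max_mods, "B")
  )
  if (all(is.na(ks))) NA_integer_ else as.integer(min(ks, na.rm = TRUE))
}

# Vectorised two-sided exact p for every table with arm totals (nA, nB):
# returns a data frame with one row per attainable table. Shared by the
# exhaustive audits below; per margin pair the hypergeometric support is
# enumerated once per event total K and p-values are read off a cumulative
# sum of the sorted point probabilities.
fisher_p_margin_pair <- function(nA, nB, tie_tol = 1e-7) {
  out_a <- integer(0); out_c <- integer(0); out_p <- numeric(0)
  for (K in 0:(nA + nB)) {
    lo <- max(0L, K - nB); hi <- min(K, nA)
    xs <- lo:hi
    if (length(xs) == 1L) {
      p <- 1
    } else {
      probs <- stats::dhyper(xs, nA, nB, K)
      ord <- order(probs)
      cs <- cumsum(probs[ord])
      idx <- findInterval(probs * (1 + tie_tol), probs[ord])
      p <- pmin(1, cs[idx])
    }
    out_a <- c(out_a, xs); out_c <- c(out_c, K - xs); out_p <- c(out_p, p)
  }
  data.frame(events_a = out_a, nonevents_a = nA - out_a,
             events_b = out_c, nonevents_b = nB - out_c, p = out_p)
}

#' Exhaustive audit of the Fragility Index search over small tables
#'
#' Enumerates every 2x2 table with both arm totals between 1 and `max_arm`,
#' computes the exact two-sided p-value for each, and for every significant
#' table runs both the sequential fewer-events-arm search
#' ([fragility_index()]) and the exhaustive single-arm oracle
#' ([fragility_index_bruteforce()]). Tables where the fewer-events-arm
#' convention does not attain the exhaustive minimum over both arms are
#' catalogued rather than hidden.
#'
#' @param max_arm Largest arm total enumerated.
#' @param alpha Significance threshold.
#'
#' @details Extreme tables exist (for example when the fewer-events arm holds
#'   no non-events at all) where the sequential rule saturates; these receive
#'   `fi = NA` and are catalogued among the divergences together with any
#'   table where the fewer-events convention does not attain the two-arm
#'   exhaustive minimum.
#'
#' @return A list of class `fi_exhaustive_check`:
#'   * `significant` — tibble of all significant tables with columns
#'     `events_a`..`nonevents_b`, `p_initial`, `fi`, `modified_arm`,
#'     `p_final`, `p_penultimate`, `fi_bruteforce_same_arm`,
#'     `fi_bruteforce_min`;
#'   * `divergences` — the subset where `fi != fi_bruteforce_min`;
#'   * `n_tables`, `n_significant`, `max_arm`, `alpha`.
#' @export
fi_exhaustive_check <- function(max_arm = 25L, alpha = 0.05) {
  grids <- vector("list", max_arm * max_arm)
  k <- 0L
  for (nA in 1:max_arm) {
    for (nB in 1:max_arm) {
      k <- k + 1L
      grids[[k]] <- fisher_p_margin_pair(nA, nB)
    }
  }
  all_tab <- do.call(rbind, grids)
  sig <- all_tab[all_tab$p < alpha, , drop = FALSE]
  n_sig <- nrow(sig)
  fi <- integer(n_sig); arm <- character(n_sig)
  p_final <- numeric(n_sig); p_pen <- numeric(n_sig)
  bf_same <- integer(n_sig); bf_min <- integer(n_sig)
  for (i in seq_len(n_sig)) {
    a <- sig$events_a[i]; b <- sig$nonevents_a[i]
    c <- sig$events_b[i]; d <- sig$nonevents_b[i]
    res <- tryCatch(
      fragility_index(c(a, b, c, d), alpha = alpha),
      fragility_saturation_error = function(e) e
    )
    if (inherits(res, "fragility_saturation_error")) {
      # the fewer-events arm exhausted its non-events while still
      # significant; catalogued below as a divergence from the oracle
      fi[i] <- NA_integer_
      arm[i] <- res$arm
      p_final[i] <- NA_real_
      p_pen[i] <- NA_real_
      bound <- max(b, d)
      bf_same[i] <- bf_arm(a, b, c, d, alpha, bound, res$arm)
      other <- if (res$arm == "A") "B" else "A"
      bf_other <- bf_arm(a, b, c, d, alpha, bound, other)
      bf_min[i] <- suppressWarnings(as.integer(min(bf_same[i], bf_other, na.rm = TRUE)))
      next
    }
    fi[i] <- res$fi
    # fi = 0 can only arise here through a last-bit rounding disagreement at
    # the alpha boundary; fall back to the fewer-events arm for the oracle
    arm[i] <- if (is.na(res$modified_arm)) (if (a <= c) "A" else "B") else res$modified_arm
    p_final[i] <- res$p_final
    p_pen[i] <- if (res$fi > 1L) res$trajectory[[res$fi - 1L]]$p else res$p_initial
    bound <- max(b, d)
    bf_same[i] <- bf_arm(a, b, c, d, alpha, bound, arm[i])
    other <- if (arm[i] == "A") "B" else "A"
    bf_other <- bf_arm(a, b, c, d, alpha, bound, other)
    bf_min[i] <- suppressWarnings(as.integer(min(bf_same[i], bf_other, na.rm = TRUE)))
  }
  sig <- tibble::as_tibble(sig)
  names(sig)[names(sig) == "p"] <- "p_initial"
  sig$fi <- fi
  sig$modified_arm <- arm
  sig$p_final <- p_final
  sig$p_penultimate <- p_pen
  sig$fi_bruteforce_same_arm <- bf_same
  sig$fi_bruteforce_min <- bf_min
  diverged <- is.na(sig$fi) | sig$fi != sig$fi_bruteforce_min
  structure(
    list(
      significant = sig,
      divergences = sig[diverged, , drop = FALSE],
      n_tables = nrow(all_tab),
      n_significant = n_sig,
      max_arm = max_arm,
      alpha = alpha
    ),
    class = "fi_exhaustive_check"
  )
}

#' @export
print.fi_exhaustive_check <- function(x, ...) {
  cat(sprintf(
    "Exhaustive FI audit: arm totals <= %d, alpha = %g\n  %d tables, %d significant, %d divergence(s) from the two-arm exhaustive minimum\n",
    x$max_arm, x$alpha, x$n_tables, x$n_significant, nrow(x$divergences)))
  invisible(x)
}
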