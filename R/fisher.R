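# Exact inference on a single 2x2 outcome table.
#
# The table layout used throughout the package is
#
#              events  non-events
#   arm A        a         b        (arm total nA = a + b)
#   arm B        c         d        (arm total nB = c + d)
#
# Arm A is the experimental/intervention arm, arm B the control/comparator.

#' Construct a 2x2 contingency table for a binary trial outcome
#'
#' Represents one trial's dichotomous primary outcome as counts of events and
#' non-events in each of two parallel arms. All downstream fragility
#' computations operate on this object.
#'
#' @param events_a,nonevents_a Number of events / non-events in arm A
#'   (experimental). Non-negative integers.
#' @param events_b,nonevents_b Number of events / non-events in arm B
#'   (control). Non-negative integers.
#'
#' @return An object of class `contingency_table`: a named integer vector with
#'   elements `events_a`, `nonevents_a`, `events_b`, `nonevents_b`.
#'
#' @details Both arm totals must be at least 1; individual cells may be zero.
#'   The total sample size is the sum of the four cells.
#'
#' @examples
#' contingency_table(5, 5, 5, 5)
#' contingency_table(1, 9, 9, 1)
#' @export
contingency_table <- function(events_a, nonevents_a, events_b, nonevents_b) {
  cells <- c(
    events_a = events_a, nonevents_a = nonevents_a,
    events_b = events_b, nonevents_b = nonevents_b
  )
  if (length(cells) != 4L || anyNA(cells)) {
    stop("all four cell counts must be supplied and non-missing", call. = FALSE)
  }
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  cells <- as.integer(round(cells))
  if (cells[1] + cells[2] < 1L || cells[3] + cells[4] < 1L) {
    stop("each arm must contain at least one patient", call. = FALSE)
  }
  structure(cells, class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(unclass(x), nrow = 2, byrow = TRUE,
              dimnames = list(c("arm A", "arm B"), c("events", "non-events")))
  cat("2x2 outcome table (n =", sum(x), ")\n")
  print(m)
  invisible(x)
}

as_contingency_table <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.numeric(x) && length(x) == 4L) {
    return(contingency_table(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  stop("cannot interpret input as a 2x2 contingency table", call. = FALSE)
}

# Fast unvalidated two-sided exact p for cells (a, b, c, d).
#
# Conditional on the margins, the events-in-arm-A cell follows a
# hypergeometric law; the two-sided p sums the point probabilities of every
# same-margin table whose probability does not exceed the observed one, with
# a 1e-7 relative buffer so floating-point representations of exact ties are
# still counted (the convention of mainstream exact-test implementations).
p2x2 <- function(a, b, c, d, tie_tol = 1e-7) {
  nA <- a + b
  nB <- c + d
  K <- a + c
  lo <- max(0L, K - nB)
  hi <- min(K, nA)
  if (lo == hi) return(1) # degenerate margin: a single attainable table
  probs <- stats::dhyper(lo:hi, nA, nB, K)
  obs <- probs[[a - lo + 1L]]
  min(1, sum(probs[probs <= obs * (1 + tie_tol)]))
}

#' Two-sided Fisher's exact test p-value
#'
#' Computes the exact two-sided p-value for a 2x2 table by hypergeometric
#' enumeration: conditional on the observed margins, every attainable table
#' whose point probability does not exceed the observed table's contributes
#' its probability to the sum.
#'
#' @param table A [contingency_table()], or a numeric vector of length 4 in
#'   the order (events_a, nonevents_a, events_b, nonevents_b).
#' @param tie_tol Relative tolerance used when comparing point probabilities,
#'   guarding against floating-point representation of exact ties. A table
#'   counts toward the p-value when its probability is at most
#'   `observed * (1 + tie_tol)`.
#'
#' @return The two-sided exact p-value, a number in (0, 1]. Degenerate margins
#'   (an outcome column or arm total of zero, so only one table is attainable)
#'   return 1.
#'
#' @examples
#' fisher_exact_two_sided(contingency_table(1, 9, 9, 1)) # 202/184756
#' fisher_exact_two_sided(contingency_table(5, 5, 5, 5)) # 1
#' @export
fisher_exact_two_sided <- function(table, tie_tol = 1e-7) {
  t <- as_contingency_table(table)
  p2x2(t[[1]], t[[2]], t[[3]], t[[4]], tie_tol = tie_tol)
}
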