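# Corpus-level aggregation: per-category and overall median/IQR of the
# Fragility Index and of loss to follow-up, and the LTFU > FI robustness flag.

#' Median and quartiles of a numeric vector
#'
#' Returns (Q1, median, Q3) under linear interpolation between order
#' statistics (the default of mainstream statistical software; quantile
#' type 7). The median is the middle order statistic for odd n and the mean
#' of the two middle ones for even n.
#'
#' @param values Non-empty numeric vector without missing values.
#' @return Named numeric vector `c(q1, median, q3)`.
#' @examples
#' quantile_triplet(c(1, 2, 3, 4, 5)) # 2, 3, 4
#' quantile_triplet(c(0, 22, 11, 12)) # median 11.5
#' @export
quantile_triplet <- function(values) {
  if (length(values) == 0) stop("cannot summarize an empty vector", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[[1]], median = q[[2]], q3 = q[[3]])
}

#' Fragility Index and LTFU flag for every trial of a corpus
#'
#' Runs [fragility_index()] on each record's 2x2 outcome table and compares
#' the result with the trial's loss to follow-up. A trial is flagged when
#' strictly more patients were lost to follow-up than its Fragility Index:
#' the unknown outcomes of the lost patients alone could then overturn the
#' result.
#'
#' @param records Corpus tibble; every record must be eligible
#'   (see [validate_trial()]).
#' @param alpha Significance threshold passed to [fragility_index()]. Always
#'   supplied explicitly or defaulted; never inferred from a record's
#'   reported p-value.
#'
#' @return Tibble with one row per trial: `study_id`, `fi`, `p_initial`,
#'   `lost_to_followup`, `ltfu_exceeds_fi`.
#' @export
score_corpus <- function(records, alpha = 0.05) {
  if (nrow(records) == 0) stop("cannot score an empty corpus", call. = FALSE)
  verdicts <- validate_corpus(records)
  if (any(!verdicts$eligible)) {
    bad <- verdicts[!verdicts$eligible, ]
    stop("ineligible record(s) in corpus: ",
         paste(sprintf("%s [%s]", bad$study_id, bad$reasons), collapse = ", "),
         call. = FALSE)
  }
  res <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    fragility_index(
      c(r$events_a, r$n_a - r$events_a, r$events_b, r$n_b - r$events_b),
      alpha = alpha
    )
  })
  fi <- vapply(res, `[[`, integer(1), "fi")
  tibble::tibble(
    study_id = records$study_id,
    fi = fi,
    p_initial = vapply(res, `[[`, numeric(1), "p_initial"),
    lost_to_followup = records$lost_to_followup,
    ltfu_exceeds_fi = records$lost_to_followup > fi
  )
}

#' Per-category and overall fragility summary of a scored corpus
#'
#' Aggregates per-trial Fragility Indices and loss-to-follow-up counts into
#' median/IQR summaries per treatment category and overall, and flags
#' categories whose median LTFU strictly exceeds their median FI — the
#' categories whose evidence could plausibly be overturned by the patients
#' whose outcomes were never observed.
#'
#' @param scored Output of [score_corpus()].
#' @param records The corpus the scores were computed from (supplies
#'   `treatment_category`); aligned to `scored` by `study_id`.
#'
#' @return A list of class `corpus_summary`:
#'   * `per_category` — tibble `treatment_category`, `n_studies`,
#'     `median_fi`, `fi_q1`, `fi_q3`, `median_ltfu`, `ltfu_q1`, `ltfu_q3`,
#'     `flagged`; categories with zero studies are omitted;
#'   * `overall` — one-row tibble with the same summary columns over all
#'     studies;
#'   * `flagged_categories` — character vector of flagged categories.
#' @export
summarize_corpus <- function(scored, records) {
  if (nrow(scored) == 0) stop("cannot summarize an empty corpus", call. = FALSE)
  idx <- match(scored$study_id, records$study_id)
  if (anyNA(idx)) {
    stop("scored studies missing from the corpus: ",
         paste(scored$study_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  dat <- tibble::tibble(
    treatment_category = records$treatment_category[idx],
    fi = scored$fi,
    ltfu = scored$lost_to_followup
  )
  summarize_block <- function(d) {
    qf <- quantile_triplet(d$fi)
    ql <- quantile_triplet(d$ltfu)
    tibble::tibble(
      n_studies = nrow(d),
      median_fi = qf[["median"]], fi_q1 = qf[["q1"]], fi_q3 = qf[["q3"]],
      median_ltfu = ql[["median"]], ltfu_q1 = ql[["q1"]], ltfu_q3 = ql[["q3"]],
      flagged = ql[["median"]] > qf[["median"]]
    )
  }
  per_category <- dat |>
    dplyr::group_by(.data$treatment_category) |>
    dplyr::group_modify(~ summarize_block(.x)) |>
    dplyr::ungroup()
  # present categories in vocabulary order, not alphabetically
  per_category <- per_category[
    order(match(per_category$treatment_category, treatment_categories())), ]
  overall <- summarize_block(dat)
  structure(
    list(
      per_category = per_category,
      overall = overall,
      flagged_categories = per_category$treatment_category[per_category$flagged]
    ),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf("Corpus fragility summary: %d studies in %d categories\n",
              x$overall$n_studies, nrow(x$per_category)))
  cat(sprintf("  overall median FI %.4g (IQR %.4g-%.4g), median LTFU %.4g (IQR %.4g-%.4g)\n",
              x$overall$median_fi, x$overall$fi_q1, x$overall$fi_q3,
              x$overall$median_ltfu, x$overall$ltfu_q1, x$overall$ltfu_q3))
  if (length(x$flagged_categories) > 0) {
    cat("  flagged (median LTFU > median FI):",
        paste(x$flagged_categories, collapse = "; "), "\n")
  } else {
    cat("  no category flagged (median LTFU > median FI)\n")
  }
  print(x$per_category)
  invisible(x)
}

#' Write summary tables to CSV
#'
#' Writes the per-category summary and the one-row overall summary as tidy
#' CSV files into `dir`.
#'
#' @param summary A [summarize_corpus()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the two file paths, invisibly.
#' @export
render_summary_tables <- function(summary, dir) {
  stopifnot(inherits(summary, "corpus_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    per_category = file.path(dir, "summary_per_category.csv"),
    overall = file.path(dir, "summary_overall.csv")
  )
  readr::write_csv(summary$per_category, paths[["per_category"]], progress = FALSE)
  readr::write_csv(summary$overall, paths[["overall"]], progress = FALSE)
  invisible(paths)
}

#' Bar chart of median Fragility Index by treatment category
#'
#' @param summary A [summarize_corpus()] result.
#' @return A ggplot object; error bars span the IQR.
#' @export
plot_fi_by_category <- function(summary) {
  stopifnot(inherits(summary, "corpus_summary"))
  d <- summary$per_category
  d$treatment_category <- factor(d$treatment_category,
                                 levels = rev(d$treatment_category))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment_category,
                                  y = .data$median_fi)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fi_q1, ymax = .data$fi_q3),
                           width = 0.25) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Fragility Index (median, IQR)") +
    ggplot2::theme_minimal()
}

#' Paired bars of median FI and median LTFU by treatment category
#'
#' Visual analogue of the robustness criterion: a category whose LTFU bar
#' exceeds its FI bar rests on results that lost patients alone could
#' overturn.
#'
#' @param summary A [summarize_corpus()] result.
#' @return A ggplot object.
#' @export
plot_fi_vs_ltfu <- function(summary) {
  stopifnot(inherits(summary, "corpus_summary"))
  d <- summary$per_category
  long <- tibble::tibble(
    treatment_category = rep(d$treatment_category, 2L),
    measure = rep(c("median FI", "median LTFU"), each = nrow(d)),
    value = c(d$median_fi, d$median_ltfu)
  )
  long$treatment_category <- factor(long$treatment_category,
                                    levels = rev(d$treatment_category))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$treatment_category,
                                     y = .data$value, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c("median FI" = "steelblue",
                                          "median LTFU" = "indianred")) +
    ggplot2::labs(x = NULL, y = "patients", fill = NULL) +
    ggplot2::theme_minimal()
}
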