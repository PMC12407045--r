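# Trial-corpus data model: one row per randomized controlled trial, mirroring
# a standard extraction form (arms, events, loss to follow-up, metadata).

#' Closed vocabulary of treatment categories
#'
#' The nine treatment modalities under which guideline-cited rectal-cancer
#' trials are grouped. Unknown category strings fail validation rather than
#' silently forming new groups.
#'
#' @return Character vector of the nine category labels.
#' @export
treatment_categories <- function() {
  c(
    "neoadjuvant chemotherapy",
    "neoadjuvant radiotherapy",
    "neoadjuvant chemoradiation",
    "neoadjuvant immunotherapy",
    "surgical intervention",
    "metastatic liver disease treatment",
    "adjuvant chemotherapy",
    "adjuvant immunotherapy",
    "follow-up and chemoprevention"
  )
}

# Versioned corpus CSV schema. Arm A = experimental/intervention,
# arm B = control/comparator.
corpus_columns <- function() {
  c(
    study_id = "character",
    short_name = "character",
    publication_year = "integer",
    country = "character",
    setting = "character",
    treatment_category = "character",
    outcome_label = "character",
    n_arms = "integer",
    events_a = "integer",
    n_a = "integer",
    events_b = "integer",
    n_b = "integer",
    lost_to_followup = "integer",
    reported_significant = "logical",
    reported_p = "double"
  )
}

#' Construct a single trial record
#'
#' Builds a one-row tibble in the corpus schema. `lost_to_followup` counts
#' randomized patients whose outcome was never ascertained
#' (randomized-but-unanalyzed; protocols differ in whether withdrawals are
#' included, and the field carries whichever convention the extractor used).
#'
#' @param study_id Unique label for the trial.
#' @param short_name Trial acronym, or `"NR"` when not reported. `"NR"` is a
#'   sentinel and never participates in duplicate matching.
#' @param publication_year Publication year (1950--2100).
#' @param country,setting,outcome_label Free-text metadata; `setting` is
#'   `"single center"` or `"multicenter"`.
#' @param treatment_category One of [treatment_categories()].
#' @param n_arms Number of randomized arms (eligible trials have exactly 2).
#' @param events_a,n_a Events and arm size in arm A (experimental).
#' @param events_b,n_b Events and arm size in arm B (control).
#' @param lost_to_followup Randomized patients without outcome ascertainment.
#' @param reported_significant Did the publication report the outcome as
#'   statistically significant? Eligibility screens on this flag, not on the
#'   recomputed exact p-value.
#' @param reported_p Reported p-value (advisory metadata only; may be `NA`).
#'
#' @return A one-row tibble with the 15 schema columns.
#' @export
trial_record <- function(study_id, short_name = "NR", publication_year,
                         country = "NR", setting = "multicenter",
                         treatment_category, outcome_label = "NR",
                         n_arms = 2L, events_a, n_a, events_b, n_b,
                         lost_to_followup = 0L, reported_significant = TRUE,
                         reported_p = NA_real_) {
  rec <- tibble::tibble(
    study_id = as.character(study_id),
    short_name = as.character(short_name),
    publication_year = as.integer(publication_year),
    country = as.character(country),
    setting = as.character(setting),
    treatment_category = as.character(treatment_category),
    outcome_label = as.character(outcome_label),
    n_arms = as.integer(n_arms),
    events_a = as.integer(events_a),
    n_a = as.integer(n_a),
    events_b = as.integer(events_b),
    n_b = as.integer(n_b),
    lost_to_followup = as.integer(lost_to_followup),
    reported_significant = as.logical(reported_significant),
    reported_p = as.numeric(reported_p)
  )
  problems <- record_structure_problems(rec)
  if (length(problems) > 0) {
    stop("invalid trial record: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  rec
}

# Structural problems (distinct from eligibility): impossible counts, unknown
# category, implausible year. Missing outcome counts are NOT structural —
# they are an eligibility matter.
record_structure_problems <- function(rec) {
  problems <- character(0)
  num <- function(x) !is.na(x)
  if (num(rec$events_a) && rec$events_a < 0) problems <- c(problems, "events_a < 0")
  if (num(rec$events_b) && rec$events_b < 0) problems <- c(problems, "events_b < 0")
  if (num(rec$n_a) && rec$n_a < 1) problems <- c(problems, "n_a < 1")
  if (num(rec$n_b) && rec$n_b < 1) problems <- c(problems, "n_b < 1")
  if (num(rec$events_a) && num(rec$n_a) && rec$events_a > rec$n_a) {
    problems <- c(problems, sprintf("events_a (%d) > n_a (%d)", rec$events_a, rec$n_a))
  }
  if (num(rec$events_b) && num(rec$n_b) && rec$events_b > rec$n_b) {
    problems <- c(problems, sprintf("events_b (%d) > n_b (%d)", rec$events_b, rec$n_b))
  }
  if (num(rec$lost_to_followup)) {
    if (rec$lost_to_followup < 0) problems <- c(problems, "lost_to_followup < 0")
    if (num(rec$n_a) && num(rec$n_b) &&
        rec$lost_to_followup > rec$n_a + rec$n_b) {
      problems <- c(problems, "lost_to_followup exceeds total randomized")
    }
  }
  if (!is.na(rec$treatment_category) &&
      !rec$treatment_category %in% treatment_categories()) {
    problems <- c(problems,
                  sprintf("unknown treatment_category '%s'", rec$treatment_category))
  }
  if (!is.na(rec$publication_year) &&
      (rec$publication_year < 1950 || rec$publication_year > 2100)) {
    problems <- c(problems, "publication_year outside 1950-2100")
  }
  problems
}

#' Eligibility screening for a single trial record
#'
#' Applies the inclusion criteria of a Fragility Index audit: a parallel
#' two-arm design, an outcome reported as statistically significant, and
#' complete event/size counts for both arms. Screening uses *reported*
#' significance; the exact test is recomputed later, which is why included
#' trials can still end up with a Fragility Index of 0.
#'
#' @param record A one-row tibble (or list) in the corpus schema.
#'
#' @return A list with `eligible` (logical) and `reasons` (character vector of
#'   machine-readable rejection codes among `non_parallel_multi_arm`,
#'   `not_significant`, `missing_outcome_data`; empty iff eligible).
#'
#' @details Structurally invalid records (negative counts, events exceeding
#'   the arm size, unknown category) raise an error rather than an
#'   ineligibility verdict: they indicate extraction mistakes, not screening
#'   failures.
#' @export
validate_trial <- function(record) {
  rec <- tibble::as_tibble(record)
  if (nrow(rec) != 1L) stop("validate_trial expects a single record", call. = FALSE)
  problems <- record_structure_problems(rec)
  if (length(problems) > 0) {
    stop("structurally invalid record '", rec$study_id, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  reasons <- character(0)
  if (is.na(rec$n_arms) || rec$n_arms != 2L) {
    reasons <- c(reasons, "non_parallel_multi_arm")
  }
  if (is.na(rec$reported_significant) || !rec$reported_significant) {
    reasons <- c(reasons, "not_significant")
  }
  if (anyNA(c(rec$events_a, rec$n_a, rec$events_b, rec$n_b))) {
    reasons <- c(reasons, "missing_outcome_data")
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Screen every record of a corpus
#'
#' @param records Corpus tibble in the schema of [trial_record()].
#' @return Tibble with `study_id`, `eligible`, and `reasons` (rejection codes
#'   collapsed with `";"`, `""` when eligible).
#' @export
validate_corpus <- function(records) {
  verdicts <- lapply(seq_len(nrow(records)), function(i) {
    validate_trial(records[i, , drop = FALSE])
  })
  tibble::tibble(
    study_id = records$study_id,
    eligible = vapply(verdicts, `[[`, logical(1), "eligible"),
    reasons = vapply(verdicts, function(v) paste(v$reasons, collapse = ";"),
                     character(1))
  )
}

#' Drop superseded versions of the same trial
#'
#' Among records sharing a non-`"NR"` short name, keeps only the one with the
#' latest publication year (trials republished with longer follow-up supersede
#' their earlier reports). Records with `short_name == "NR"` never match each
#' other. Order of the retained records is stable.
#'
#' @param records Corpus tibble.
#' @return The corpus with superseded rows removed.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(records)
  keep <- rep(TRUE, nrow(records))
  named <- which(!is.na(records$short_name) & records$short_name != "NR")
  for (nm in unique(records$short_name[named])) {
    idx <- named[records$short_name[named] == nm]
    if (length(idx) > 1L) {
      best <- idx[which.max(records$publication_year[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  records[keep, , drop = FALSE]
}

#' Read a trial corpus from CSV
#'
#' Expects the versioned 15-column schema (see [trial_record()]); the header
#' is checked and structurally impossible rows are reported with their row
#' numbers.
#'
#' @param path Path to a corpus CSV.
#' @return Corpus tibble.
#' @export
read_corpus <- function(path) {
  cols <- corpus_columns()
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (length(header) == 0 || anyNA(match(names(cols), header))) {
    missing <- setdiff(names(cols), header)
    stop("corpus CSV is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  type_map <- c(character = "c", integer = "i", logical = "l", double = "d")
  spec <- do.call(readr::cols_only,
                  as.list(stats::setNames(type_map[cols], names(cols))))
  # readr's own parse warning is redundant: problems() is surfaced as a
  # row-level error just below
  records <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE)
  )
  parse_problems <- readr::problems(records)
  if (nrow(parse_problems) > 0) {
    bad <- parse_problems[1, ]
    stop(sprintf(
      "corpus CSV row %d, column '%s': cannot parse value %s (%d problem(s) in total)",
      bad$row, header[bad$col], bad$actual, nrow(parse_problems)), call. = FALSE)
  }
  records <- records[, names(cols)]
  problems <- character(0)
  for (i in seq_len(nrow(records))) {
    pr <- record_structure_problems(records[i, , drop = FALSE])
    if (length(pr) > 0) {
      problems <- c(problems, sprintf("row %d (%s): %s", i,
                                      records$study_id[i],
                                      paste(pr, collapse = "; ")))
    }
  }
  if (length(problems) > 0) {
    stop("invalid corpus rows:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  records
}

#' Write a trial corpus to CSV
#'
#' Writes the 15 schema columns in canonical order; extra columns (for
#' example the simulator's `n_redraws` diagnostic) are dropped so that the
#' file always round-trips through [read_corpus()].
#'
#' @param records Corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  cols <- names(corpus_columns())
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    stop("corpus is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(records[, cols], path, progress = FALSE)
  invisible(path)
}
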