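# End-to-end pipeline drivers: simulate a corpus, batch-score a corpus CSV,
# and record a reproducibility manifest next to every output set. These are
# the functions the numbered scripts under analysis/ call.

#' Write a run manifest
#'
#' Records what produced a set of outputs: command name, resolved
#' parameters, input and output paths, package version, seed and timestamp,
#' as JSON next to the outputs. Given the same package version, inputs and
#' seed, the outputs can be regenerated bit-identically.
#'
#' @param dir Directory the outputs live in.
#' @param command Short command name (used in the manifest filename).
#' @param params Named list of resolved parameters.
#' @param inputs,outputs Character vectors of paths.
#' @param seed Root seed, when the run was stochastic.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(dir, command, params = list(), inputs = character(0),
                           outputs = character(0), seed = NULL) {
  manifest <- list(
    command = command,
    params = params,
    inputs = as.character(inputs),
    outputs = as.character(outputs),
    package = "fragilityaudit",
    package_version = as.character(utils::packageVersion("fragilityaudit")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Simulate a corpus and write it to CSV
#'
#' @param config A [simulation_config()] or the path of a YAML configuration.
#' @param out_csv Output CSV path.
#' @param seed Optional override of the configured root seed.
#' @return The simulated corpus tibble, invisibly. Writes the corpus CSV and
#'   a `simulate_manifest.json` next to it.
#' @export
run_simulate <- function(config, out_csv, seed = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- read_sim_config(config, seed = seed)
  } else if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  stopifnot(inherits(config, "simulation_config"))
  corpus <- simulate_corpus(config)
  dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
  write_corpus(corpus, out_csv)
  write_manifest(
    dirname(out_csv), "simulate",
    params = list(alpha = config$alpha, max_resamples = config$max_resamples,
                  n_categories = length(config$categories),
                  n_studies = sum(vapply(config$categories, `[[`,
                                         integer(1), "n_studies"))),
    inputs = if (is.null(cfg_path)) character(0) else cfg_path,
    outputs = out_csv,
    seed = config$seed
  )
  invisible(corpus)
}

#' Batch fragility analysis of a corpus CSV
#'
#' The full audit pipeline: read, deduplicate, screen for eligibility, score
#' every eligible trial with [fragility_index()], and summarize per category
#' and overall. Ineligible rows are not fatal; they are written to a rejects
#' file with their rejection codes.
#'
#' @param corpus_csv Path of a corpus CSV in the [trial_record()] schema.
#' @param out_dir Output directory (created if absent).
#' @param alpha Significance threshold for the exact test.
#' @return A list with `scored` (per-study tibble), `summary`
#'   (a [summarize_corpus()] object), `rejected` (tibble of rejected rows
#'   with reasons), and `paths` (named vector of written files), invisibly.
#'
#' @details Written files: `per_study.csv` (study_id, fi, p_initial,
#'   lost_to_followup, ltfu_exceeds_fi), `summary_per_category.csv`,
#'   `summary_overall.csv`, `rejects.csv` (when any row was rejected), and
#'   `batch_manifest.json`. Floating-point columns are printed with 6
#'   significant digits for cross-platform diffability.
#' @export
run_batch <- function(corpus_csv, out_dir, alpha = 0.05) {
  records <- read_corpus(corpus_csv)
  records <- deduplicate(records)
  if (nrow(records) == 0) {
    stop("corpus '", corpus_csv, "' contains no records", call. = FALSE)
  }
  verdicts <- validate_corpus(records)
  eligible <- records[verdicts$eligible, , drop = FALSE]
  rejected <- records[!verdicts$eligible, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reject_reasons <- verdicts$reasons[!verdicts$eligible]
  }
  if (nrow(eligible) == 0) {
    stop("no eligible records remain after screening (",
         nrow(rejected), " rejected)", call. = FALSE)
  }
  scored <- score_corpus(eligible, alpha = alpha)
  summary <- summarize_corpus(scored, eligible)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  six <- function(d) dplyr::mutate(d, dplyr::across(dplyr::where(is.double),
                                                    ~ signif(.x, 6)))
  paths <- c(per_study = file.path(out_dir, "per_study.csv"))
  readr::write_csv(six(scored), paths[["per_study"]], progress = FALSE)
  paths <- c(paths, render_summary_tables(summary, out_dir))
  if (nrow(rejected) > 0) {
    paths <- c(paths, rejects = file.path(out_dir, "rejects.csv"))
    readr::write_csv(rejected, paths[["rejects"]], progress = FALSE)
  }
  write_manifest(
    out_dir, "batch",
    params = list(alpha = alpha, n_records = nrow(records),
                  n_eligible = nrow(eligible), n_rejected = nrow(rejected)),
    inputs = corpus_csv,
    outputs = unname(paths)
  )
  invisible(list(scored = scored, summary = summary, rejected = rejected,
                 paths = paths))
}
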