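# End-to-end orchestration: quantification (if OD input) -> paired pre/post
# t-tests per fluid -> agreement suite, with TSV/JSON report emission and a
# run manifest.

#' Configure a pipeline run
#'
#' @param input_path Path to the input CSV.
#' @param input_kind `"od"` (raw absorbances, quantified first) or
#'   `"concentrations"` (either the stacked per-fluid schema of
#'   [quantify_od_table()] or the wide paired schema of [cohort_pairs()]).
#' @param alpha Significance level for all intervals and tests.
#' @param bonferroni_family Family size for Bonferroni adjustment of
#'   correlation and t-test p-values (1 = none).
#' @param ci_method OLP confidence-interval method, `"analytic"` or
#'   `"bootstrap"`.
#' @param bootstrap_reps Bootstrap replicates (>= 1000) when
#'   `ci_method = "bootstrap"`.
#' @param seed Seed applied before any stochastic step (bootstrap).
#' @param output_dir Directory for report files (created if needed).
#' @param clamp_negative_od Passed to [quantify_od_table()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(input_path, input_kind = c("concentrations", "od"),
                       alpha = 0.05, bonferroni_family = 1,
                       ci_method = c("analytic", "bootstrap"),
                       bootstrap_reps = 20000, seed = 1,
                       output_dir = ".", clamp_negative_od = FALSE) {
  input_kind <- match.arg(input_kind)
  ci_method <- match.arg(ci_method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (ci_method == "bootstrap" && bootstrap_reps < 1000)
    stop("bootstrap_reps must be >= 1000", call. = FALSE)
  structure(list(input_path = input_path, input_kind = input_kind,
                 alpha = alpha, bonferroni_family = bonferroni_family,
                 ci_method = ci_method, bootstrap_reps = bootstrap_reps,
                 seed = as.integer(seed), output_dir = output_dir,
                 clamp_negative_od = clamp_negative_od),
            class = "run_config")
}

#' Run the full quantification-and-agreement pipeline
#'
#' Reads the input, quantifies absorbances if needed, runs paired pre/post
#' t-tests per fluid and the agreement suite per stratum, and writes:
#' `concentrations.csv` (OD input only), `ttests.tsv`, `agreement.tsv`,
#' `bland_altman.tsv`, `summary.json` and `manifest.json` into
#' `output_dir`. Deterministic for a fixed config and seed.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `concentrations` (or NULL), `pairs`,
#'   `ttests`, `agreement` (the [agreement_suite()] object), `warnings`,
#'   and `files` (paths written).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config"))
    stop("cfg must come from run_config()", call. = FALSE)
  if (!file.exists(cfg$input_path))
    stop("input not readable: ", cfg$input_path, call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  warns <- character()
  note <- function(w) warns[[length(warns) + 1L]] <<- w
  files <- character()

  message("stage=read input=", cfg$input_path, " kind=", cfg$input_kind)
  raw <- utils::read.csv(cfg$input_path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  conc <- NULL
  if (cfg$input_kind == "od") {
    conc <- withCallingHandlers(
      quantify_od_table(raw, clamp_negative_od = cfg$clamp_negative_od),
      warning = function(w) { note(conditionMessage(w))
                              invokeRestart("muffleWarning") })
    message("stage=quantify rows=", nrow(conc))
    f <- file.path(cfg$output_dir, "concentrations.csv")
    write_concentrations_csv(conc, f)
    files <- c(files, f)
    pairs <- cohort_pairs(conc)
  } else if (all(c("plasma", "saliva") %in% names(raw))) {
    pairs <- cohort_pairs(raw)
  } else {
    conc <- raw
    pairs <- cohort_pairs(raw)
  }

  # per-fluid pre/post t-tests from the paired layout
  long <- rbind(
    data.frame(pairs[c("subject_id", "cycle_phase", "timepoint", "analyte")],
               fluid = "plasma", value = pairs$plasma,
               stringsAsFactors = FALSE),
    data.frame(pairs[c("subject_id", "cycle_phase", "timepoint", "analyte")],
               fluid = "saliva", value = pairs$saliva,
               stringsAsFactors = FALSE))
  tt <- withCallingHandlers(
    tryCatch(paired_t_table(long, bonferroni_family = cfg$bonferroni_family),
             error = function(e) { note(conditionMessage(e)); NULL }),
    warning = function(w) { note(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  if (!is.null(tt)) {
    message("stage=ttests rows=", nrow(tt))
    f <- file.path(cfg$output_dir, "ttests.tsv")
    utils::write.table(tt, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  agr <- withCallingHandlers(
    agreement_suite(pairs, alpha = cfg$alpha,
                    bonferroni_family = cfg$bonferroni_family,
                    ci_method = cfg$ci_method),
    warning = function(w) { note(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  message("stage=agreement rows=", nrow(agr$table))
  f1 <- file.path(cfg$output_dir, "agreement.tsv")
  utils::write.table(agr$table, f1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f2 <- file.path(cfg$output_dir, "bland_altman.tsv")
  utils::write.table(agr$bland_altman, f2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files <- c(files, f1, f2)

  summary_obj <- list(
    alpha = cfg$alpha, bonferroni_family = cfg$bonferroni_family,
    ci_method = cfg$ci_method, n_strata = nrow(agr$table),
    agreement = agr$table, bland_altman = agr$bland_altman,
    ttests = tt, warnings = warns)
  f3 <- file.path(cfg$output_dir, "summary.json")
  jsonlite::write_json(summary_obj, f3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  manifest <- list(
    config = unclass(cfg),
    version = as.character(utils::packageVersion("lpoagree")),
    rows_in = nrow(raw), n_strata = nrow(agr$table),
    n_warnings = length(warns), files = basename(c(files, f3)))
  f4 <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, f4, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- c(files, f3, f4)
  message("stage=done files=", length(files), " warnings=", length(warns))
  invisible(list(concentrations = conc, pairs = pairs, ttests = tt,
                 agreement = agr, warnings = warns, files = files))
}
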