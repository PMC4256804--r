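#' Validate an end-to-end pipeline configuration
#'
#' Bundles input locations (or in-memory tables), output directory and all
#' stage parameters, validating them before any work is done.
#'
#' @param survey A survey table (data frame) or path to a survey CSV.
#' @param codebook A `crcs_codebook` or path to a codebook CSV.
#' @param out_dir Output directory for all artifacts.
#' @param min_support Mining threshold (default 0.6).
#' @param strong_high,strong_low Strong-itemset thresholds (defaults 0.8,
#'   0.6); `strong_high` must be at least `strong_low`.
#' @param m1_diff Minimum M1 support difference (default 0.20).
#' @param sweep_thresholds Thresholds for the support sweep, or `NULL` to
#'   skip the sweep.
#' @param regression A [design_spec()] or `NULL` to skip the regression
#'   stage.
#' @param outcome Outcome column name in the survey table.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(survey, codebook, out_dir,
                            min_support = 0.6, strong_high = 0.8,
                            strong_low = 0.6, m1_diff = 0.20,
                            sweep_thresholds = NULL, regression = NULL,
                            outcome = "adherence", seed = 1L) {
  thresholds <- c(min_support, strong_high, strong_low,
                  sweep_thresholds %||% numeric(0))
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("all support thresholds must lie in (0, 1]")
  }
  if (m1_diff < 0 || m1_diff > 1) abort("`m1_diff` must be in [0, 1]")
  if (strong_high < strong_low) {
    abort("`strong_high` must be at least `strong_low`")
  }
  if (!is.null(regression) && !inherits(regression, "design_spec")) {
    abort("`regression` must be a design_spec() or NULL")
  }
  structure(
    list(
      survey = survey, codebook = codebook, out_dir = out_dir,
      min_support = min_support, strong_high = strong_high,
      strong_low = strong_low, m1_diff = m1_diff,
      sweep_thresholds = sweep_thresholds, regression = regression,
      outcome = outcome, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full mining pipeline
#'
#' Sequences the stages encode -> mine per class -> maximal filter ->
#' contrast rules -> (optional) regression, writing each artifact under the
#' configured output directory: `transactions.jsonl`, per-class
#' `frequent_<class>.tsv`, the contrast report, the regression report, an
#' optional `support_sweep.tsv`, and `manifest.json` with the configuration
#' hash, seed and per-stage counts. Deterministic: rerunning the same
#' configuration reproduces the same manifest. On failure, partially
#' written outputs are removed.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  survey <- if (is.character(config$survey)) {
    readr::read_csv(config$survey, show_col_types = FALSE)
  } else {
    config$survey
  }
  codebook <- if (is.character(config$codebook)) {
    read_codebook(config$codebook)
  } else {
    config$codebook
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit({
    if (!ok) unlink(written, recursive = TRUE)
  })
  track <- function(path) {
    written <<- c(written, path)
    path
  }

  tx <- encode_responses(survey, codebook, outcome = config$outcome)
  write_transactions(tx, track(file.path(config$out_dir, "transactions.jsonl")))

  tabs <- lapply(CLASS_LEVELS, function(cl) {
    tab <- apriori_itemsets(tx, cl, config$min_support)
    flagged <- maximal_itemsets(tab, keep_all = TRUE)
    write_itemsets(flagged,
                   track(file.path(config$out_dir, paste0("frequent_", cl, ".tsv"))),
                   codebook = codebook)
    flagged
  })
  names(tabs) <- CLASS_LEVELS

  report <- contrast_report(
    tx,
    min_support = config$min_support,
    strong_high = config$strong_high,
    strong_low = config$strong_low,
    m1_diff = config$m1_diff
  )
  cdir <- file.path(config$out_dir, "contrast")
  write_contrast_report(report, cdir, codebook = codebook)
  track(cdir)

  sweep <- NULL
  if (!is.null(config$sweep_thresholds)) {
    sweep <- support_sweep(tx, config$sweep_thresholds)
    readr::write_tsv(sweep,
                     track(file.path(config$out_dir, "support_sweep.tsv")))
  }

  fit <- NULL
  if (!is.null(config$regression)) {
    design <- encode_design(survey, config$regression, codebook = codebook)
    fit <- fit_adherence_model(design)
    rdir <- file.path(config$out_dir, "regression")
    write_regression_report(fit, rdir)
    track(rdir)
  }

  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    params = config[c("min_support", "strong_high", "strong_low", "m1_diff")],
    counts = list(
      n_records = nrow(tx),
      n_dropped = attr(tx, "n_dropped"),
      n1 = unname(class_sizes(tx)["n1"]),
      n2 = unname(class_sizes(tx)["n2"]),
      n_frequent_c1 = nrow(tabs$adherent),
      n_frequent_c2 = nrow(tabs$non_adherent),
      n_maximal_c1 = sum(tabs$adherent$is_maximal),
      n_maximal_c2 = sum(tabs$non_adherent$is_maximal),
      n_strong_c1 = sum(report$strong$class == "adherent"),
      n_strong_c2 = sum(report$strong$class == "non_adherent"),
      n_m1 = nrow(report$m1),
      n_m2 = nrow(report$m2),
      n_regression = if (is.null(fit)) NA_integer_ else fit$n_used
    )
  )
  jsonlite::write_json(manifest,
                       track(file.path(config$out_dir, "manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  invisible(c(manifest, list(
    transactions = tx, tables = tabs, contrast = report,
    sweep = sweep, fit = fit
  )))
}
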