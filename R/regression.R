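#' Specify the confirmatory regression design
#'
#' Records which column is the binary outcome and how each mining-selected
#' survey question enters the model: `"indicator"` predictors become 0/1
#' flags (1 when the response equals `reference`), `"ordinal"` predictors
#' become the integer option index, and `"numeric"` columns are used as-is.
#' Missing-data policy is listwise deletion.
#'
#' @param outcome Name of the outcome column (factor/character with levels
#'   `adherent` / `non_adherent`, or 0/1 numeric).
#' @param predictors A data frame with columns `variable` (column name in
#'   the survey/design table), `coding` (one of `"indicator"`, `"ordinal"`,
#'   `"numeric"`), and optionally `reference` (the level coded 1 for
#'   indicators). Duplicate variables are an error.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(outcome, predictors) {
  stopifnot(is.data.frame(predictors), "variable" %in% names(predictors),
            "coding" %in% names(predictors))
  if (anyDuplicated(predictors$variable)) {
    abort("duplicate predictor variables in design")
  }
  bad <- !predictors$coding %in% c("indicator", "ordinal", "numeric")
  if (any(bad)) {
    abort(paste0("unknown coding: ",
                 paste(unique(predictors$coding[bad]), collapse = ", ")))
  }
  if (!"reference" %in% names(predictors)) predictors$reference <- NA_character_
  structure(
    list(outcome = outcome, predictors = tibble::as_tibble(predictors)),
    class = "design_spec"
  )
}

#' Build the numeric model table for a design
#'
#' Applies the predictor codings of a [design_spec()] to a raw survey table
#' and returns the outcome (0/1, with 1 = adherent) plus one numeric column
#' per predictor. For `"ordinal"` codings a codebook is needed to map option
#' labels to option indices.
#'
#' @param data Raw survey/design table.
#' @param spec A [design_spec()].
#' @param codebook Optional codebook (required for ordinal codings of
#'   question columns named `Q<id>`).
#' @return A tibble with `.outcome` plus the coded predictor columns.
#' @export
encode_design <- function(data, spec, codebook = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  if (!spec$outcome %in% names(data)) {
    abort(paste0("outcome column `", spec$outcome, "` not found"))
  }
  y_raw <- data[[spec$outcome]]
  y <- if (is.numeric(y_raw)) {
    as.integer(y_raw)
  } else {
    ifelse(as.character(y_raw) == "adherent", 1L,
           ifelse(as.character(y_raw) == "non_adherent", 0L, NA_integer_))
  }
  out <- tibble::tibble(.outcome = y)
  for (i in seq_len(nrow(spec$predictors))) {
    v <- spec$predictors$variable[i]
    coding <- spec$predictors$coding[i]
    if (!v %in% names(data)) {
      abort(paste0("predictor column `", v, "` not found"))
    }
    x <- data[[v]]
    out[[v]] <- switch(
      coding,
      numeric = as.numeric(x),
      indicator = as.numeric(as.character(x) == spec$predictors$reference[i]),
      ordinal = {
        if (is.null(codebook)) abort("ordinal coding requires a codebook")
        qid <- as.integer(sub("^Q", "", v))
        cb_q <- codebook[codebook$question_id == qid, ]
        as.numeric(cb_q$option_index[match(as.character(x), cb_q$option_label)])
      }
    )
  }
  out
}

#' Fit the confirmatory adherence logistic regression
#'
#' Maximum-likelihood logistic regression of the binary adherence outcome on
#' the mining-selected predictors, fitted by iteratively reweighted least
#' squares (at most 100 iterations, relative log-likelihood convergence
#' tolerance 1e-10). Records missing the outcome or any predictor are
#' dropped listwise before fitting. Rank-deficient designs and separated
#' fits raise diagnostic errors naming the offending columns.
#'
#' @param data A data frame holding the outcome and numeric predictor
#'   columns (e.g. from [encode_design()], where the outcome column is
#'   `.outcome`).
#' @param outcome Name of the 0/1 outcome column (default `".outcome"`).
#' @param predictors Character vector of predictor column names; default all
#'   other numeric columns.
#' @return An object of class `adherence_fit`: the underlying `glm`, the
#'   data used, log-likelihoods, and `n_used`. Use [generics::tidy()] for
#'   the coefficient table and [generics::glance()] for fit statistics.
#' @export
fit_adherence_model <- function(data, outcome = ".outcome", predictors = NULL) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column `", outcome, "` not found"))
  }
  predictors <- predictors %||% setdiff(names(data), outcome)
  if (length(predictors) == 0) abort("no predictors given")
  used_cols <- c(outcome, predictors)
  complete <- complete.cases(data[, used_cols, drop = FALSE])
  d <- tibble::as_tibble(data[complete, used_cols, drop = FALSE])
  y <- d[[outcome]]
  if (!all(y %in% c(0, 1))) abort("outcome must be 0/1 after coding")
  if (length(unique(y)) < 2) {
    abort("outcome has a single level after listwise deletion")
  }

  X <- model.matrix(
    stats::reformulate(predictors),
    data = d
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }

  fml <- stats::reformulate(predictors, response = outcome)
  fit <- glm(fml, family = binomial(), data = d,
             control = glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    abort("IRLS did not converge within 100 iterations")
  }
  b <- coef(fit)[-1]
  if (any(abs(b) > 15)) {
    abort(paste0("apparent separation on predictor(s): ",
                 paste(names(b)[abs(b) > 15], collapse = ", ")))
  }

  null_fit <- glm(stats::reformulate("1", response = outcome),
                  family = binomial(), data = d)
  out <- list(
    glm = fit,
    data = d,
    outcome = outcome,
    predictors = predictors,
    n_used = nrow(d),
    ll_model = as.numeric(logLik(fit)),
    ll_null = as.numeric(logLik(null_fit))
  )
  class(out) <- "adherence_fit"
  out
}

#' @export
print.adherence_fit <- function(x, ...) {
  cat("Adherence logistic regression (n =", x$n_used, ")\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy the coefficient table of an adherence fit
#'
#' One row per model term with the log-odds coefficient `B`, its standard
#' error, the Wald statistic `(B/SE)^2` with its chi-square p-value, the
#' odds ratio `exp(B)`, and the 95% Wald interval `exp(B +/- 1.96 SE)`.
#'
#' @param x An `adherence_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`, `wald`,
#'   `p_value`, `odds_ratio`, `or_low`, `or_high`.
#' @export
tidy.adherence_fit <- function(x, ...) {
  b <- coef(x$glm)
  se <- sqrt(diag(vcov(x$glm)))
  wald <- (b / se)^2
  tibble::tibble(
    term = names(b),
    estimate = unname(b),
    std_error = unname(se),
    wald = unname(wald),
    p_value = unname(pchisq(wald, df = 1, lower.tail = FALSE)),
    odds_ratio = exp(unname(b)),
    or_low = exp(unname(b - 1.96 * se)),
    or_high = exp(unname(b + 1.96 * se))
  )
}

#' One-row summary of an adherence fit
#'
#' Combines the sample size, log-likelihoods, Cox & Snell and Nagelkerke
#' pseudo-R-squared, the Hosmer-Lemeshow test and the classification rates.
#'
#' @param x An `adherence_fit`.
#' @param hl_groups Hosmer-Lemeshow group target (default 10).
#' @param cutoff Classification cutoff (default 0.5).
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.adherence_fit <- function(x, hl_groups = 10, cutoff = 0.5, ...) {
  r2 <- pseudo_r2(x)
  hl <- hosmer_lemeshow(x, groups = hl_groups)
  ct <- classification_table(x, cutoff = cutoff)
  tibble::tibble(
    n_used = x$n_used,
    ll_null = x$ll_null,
    ll_model = x$ll_model,
    cox_snell_r2 = r2[["cox_snell"]],
    nagelkerke_r2 = r2[["nagelkerke"]],
    hl_chisq = hl[["chisq"]],
    hl_df = hl[["df"]],
    hl_p = hl[["p_value"]],
    pct_correct_class0 = ct$pct_correct_class0,
    pct_correct_class1 = ct$pct_correct_class1,
    pct_correct_overall = ct$pct_correct_overall
  )
}

#' Cox & Snell and Nagelkerke pseudo-R-squared
#'
#' `cox_snell = 1 - exp(2 (LL0 - LL1) / n)`; Nagelkerke rescales it by its
#' attainable maximum, `nagelkerke = cox_snell / (1 - exp(2 LL0 / n))`, so
#' that a perfect fit approaches 1. A null model scores 0 on both.
#'
#' @param fit An `adherence_fit`.
#' @return Named numeric vector `c(cox_snell=, nagelkerke=)`.
#' @export
pseudo_r2 <- function(fit) {
  ll0 <- fit$ll_null
  ll1 <- fit$ll_model
  n <- fit$n_used
  if (ll1 < ll0 - 1e-8) {
    abort("fitted log-likelihood below null log-likelihood; fit is inconsistent")
  }
  cox <- 1 - exp(2 * (ll0 - ll1) / n)
  max_cox <- 1 - exp(2 * ll0 / n)
  c(cox_snell = cox, nagelkerke = if (max_cox > 0) cox / max_cox else 0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Records are sorted by fitted probability and partitioned into at most
#' `groups` bins of near-equal size; records with identical fitted
#' probabilities are never split across bins, so with few binary predictors
#' the number of distinct covariate patterns can cap the group count below
#' `groups` (7 patterns give g = 7 and hence df = 5). The statistic is
#' `sum (O - E)^2 / E` over both outcome levels in every bin, with
#' `df = g - 2` and an upper-tail chi-square p-value.
#'
#' @param fit An `adherence_fit`.
#' @param groups Target number of bins (default 10).
#' @return Named numeric vector `c(chisq=, df=, p_value=, g=)`.
#' @export
hosmer_lemeshow <- function(fit, groups = 10) {
  p <- unname(stats::fitted(fit$glm))
  y <- fit$data[[fit$outcome]]
  n <- length(p)
  o <- order(p)
  p <- p[o]; y <- y[o]
  # contiguous blocks of identical fitted probability
  block <- cumsum(c(TRUE, diff(p) > 1e-12))
  block_sizes <- tabulate(block)
  cum <- cumsum(block_sizes)
  bin_of_block <- pmin(groups, ceiling(cum * groups / n))
  bin <- bin_of_block[block]
  g <- length(unique(bin))
  if (g < 3) abort("fewer than 3 distinct probability groups; test undefined")
  o1 <- tapply(y, bin, sum)
  e1 <- tapply(p, bin, sum)
  nb <- tapply(y, bin, length)
  o0 <- nb - o1
  e0 <- nb - e1
  chisq <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  df <- g - 2
  c(chisq = chisq, df = df,
    p_value = pchisq(chisq, df = df, lower.tail = FALSE), g = g)
}

#' Classification table at a probability cutoff
#'
#' Predicts class 1 when the fitted probability is at least `cutoff` and
#' reports the percent correctly classified within each observed outcome
#' level and overall.
#'
#' @param fit An `adherence_fit`.
#' @param cutoff Probability cutoff (default 0.5).
#' @return A one-row tibble: `cutoff`, `pct_correct_class0`,
#'   `pct_correct_class1`, `pct_correct_overall`.
#' @export
classification_table <- function(fit, cutoff = 0.5) {
  p <- unname(stats::fitted(fit$glm))
  y <- fit$data[[fit$outcome]]
  pred <- as.integer(p >= cutoff)
  tibble::tibble(
    cutoff = cutoff,
    pct_correct_class0 = 100 * mean(pred[y == 0] == 0),
    pct_correct_class1 = 100 * mean(pred[y == 1] == 1),
    pct_correct_overall = 100 * mean(pred == y)
  )
}

#' Write the regression report
#'
#' A TSV coefficient table (Item, B, SE(B), Wald, OR with CI) with footer
#' rows for pseudo-R-squared, the Hosmer-Lemeshow test, the classification
#' rates and n, plus a JSON twin with full precision.
#'
#' @param fit An `adherence_fit`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_regression_report <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  td <- tidy(fit)
  gl <- glance(fit)
  tab <- tibble::tibble(
    item = td$term,
    B = round(td$estimate, 4),
    SE_B = round(td$std_error, 4),
    Wald = round(td$wald, 4),
    OR_95CI = sprintf("%.2f (%.2f, %.2f)", td$odds_ratio, td$or_low, td$or_high)
  )
  readr::write_tsv(tab, file.path(dir, "regression_table.tsv"))
  footer <- c(
    sprintf("Cox & Snell R2 = %.4f; Nagelkerke R2 = %.4f",
            gl$cox_snell_r2, gl$nagelkerke_r2),
    sprintf("Hosmer-Lemeshow chi2(%d) = %.4f, p = %.4f",
            gl$hl_df, gl$hl_chisq, gl$hl_p),
    sprintf("Correctly classified: %.1f%% of class 0, %.1f%% of class 1, %.1f%% overall",
            gl$pct_correct_class0, gl$pct_correct_class1, gl$pct_correct_overall),
    sprintf("N = %d", gl$n_used)
  )
  cat(footer, file = file.path(dir, "regression_table.tsv"),
      sep = "\n", append = TRUE)
  jsonlite::write_json(
    list(coefficients = td, summary = gl),
    file.path(dir, "regression_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
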