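#' Derive screening-history flags from test-ever and years-since fields
#'
#' Guideline adherence to colorectal cancer screening rests on three
#' within-interval flags: a fecal occult blood test (FOBT) within 1 year, a
#' sigmoidoscopy within 5 years, or a colonoscopy within 10 years (guidelines
#' give colonoscopy a 7-10 year window; the 10-year outer bound is the
#' default and each interval is configurable). A flag is `FALSE` whenever the
#' test was never taken, and unknown fields (`NA` in the ever- or years-
#' columns) resolve to `FALSE` because an unknown history cannot demonstrate
#' adherence; the number of such imputations is recorded in the
#' `n_imputed` attribute.
#'
#' @param data A data frame with logical (or 0/1) columns `fobt_ever`,
#'   `sig_ever`, `col_ever` and numeric columns `fobt_years_ago`,
#'   `sig_years_ago`, `col_years_ago` (years since the most recent test).
#' @param fobt_interval,sig_interval,col_interval Maximum years since the
#'   test for it to count toward adherence.
#' @return The input tibble with logical columns `fobt_within_1y`,
#'   `sig_within_5y`, `col_within_10y` appended, and attribute `n_imputed`.
#' @export
screening_history <- function(data, fobt_interval = 1, sig_interval = 5,
                              col_interval = 10) {
  stopifnot(is.data.frame(data))
  flag <- function(ever, years, interval) {
    out <- !is.na(ever) & as.logical(ever) & !is.na(years) & years <= interval
    attr(out, "imputed") <- sum(is.na(ever) | (as.logical(ever) %in% TRUE & is.na(years)))
    out
  }
  f <- flag(data$fobt_ever, data$fobt_years_ago, fobt_interval)
  s <- flag(data$sig_ever, data$sig_years_ago, sig_interval)
  k <- flag(data$col_ever, data$col_years_ago, col_interval)
  out <- tibble::as_tibble(data)
  out$fobt_within_1y <- as.logical(f)
  out$sig_within_5y <- as.logical(s)
  out$col_within_10y <- as.logical(k)
  attr(out, "n_imputed") <-
    attr(f, "imputed") + attr(s, "imputed") + attr(k, "imputed")
  out
}

#' Classify participants as screening adherent or non-adherent
#'
#' A participant is adherent when any guideline-concordant screening is
#' reported: FOBT within the last year, sigmoidoscopy within the last five
#' years (with or without a recent FOBT), or colonoscopy within the last ten
#' years. All others are non-adherent. The rule is monotone: reporting an
#' additional qualifying screening can never turn an adherent participant
#' non-adherent. `NA` flags are treated as `FALSE` (unknown history cannot
#' demonstrate adherence); the count is recorded in attribute `n_imputed`.
#'
#' @param data A data frame with logical columns `fobt_within_1y`,
#'   `sig_within_5y`, `col_within_10y` (e.g. from [screening_history()]).
#' @return The input tibble with an `adherence` factor column
#'   (levels `"adherent"`, `"non_adherent"`) appended.
#' @export
#' @examples
#' h <- tibble::tibble(
#'   fobt_within_1y = c(TRUE, FALSE, FALSE),
#'   sig_within_5y = c(FALSE, FALSE, TRUE),
#'   col_within_10y = c(FALSE, FALSE, FALSE)
#' )
#' classify_adherence(h)$adherence
classify_adherence <- function(data) {
  stopifnot(is.data.frame(data))
  needed <- c("fobt_within_1y", "sig_within_5y", "col_within_10y")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  flags <- lapply(data[needed], function(x) {
    x <- as.logical(x)
    x[is.na(x)] <- FALSE
    x
  })
  n_imputed <- sum(vapply(data[needed], function(x) sum(is.na(x)), integer(1)))
  adherent <- flags[[1]] | flags[[2]] | flags[[3]]
  out <- tibble::as_tibble(data)
  out$adherence <- factor(
    ifelse(adherent, "adherent", "non_adherent"),
    levels = CLASS_LEVELS
  )
  attr(out, "n_imputed") <- n_imputed
  out
}
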