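#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot frequent-itemset counts across the support sweep
#'
#' Counts of frequent and maximal itemsets per class against the mining
#' threshold; both curves are non-increasing in the threshold.
#'
#' @param object A `crcs_sweep` from [support_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crcs_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("n_frequent", "n_maximal"),
    names_to = "kind", values_to = "count"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$count,
    colour = .data$class, linetype = .data$kind
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "support threshold", y = "itemset count",
      colour = "class", linetype = NULL,
      title = "Frequent itemsets across support thresholds"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a contrast report as per-class support dumbbells
#'
#' Each strong or M1 itemset is drawn as a segment from its non-adherent to
#' its adherent support, making the between-class gap that selected it
#' visible.
#'
#' @param object A [contrast_report()].
#' @param max_items Cap on the number of itemsets drawn per family.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contrast_report <- function(object, max_items = 20, ...) {
  strong <- tibble::as_tibble(object$strong)
  m1 <- tibble::as_tibble(object$m1)
  rows <- list()
  if (nrow(strong) > 0) {
    s1 <- ifelse(strong$class == "adherent",
                 strong$support_in_class, strong$support_in_other)
    s2 <- ifelse(strong$class == "adherent",
                 strong$support_in_other, strong$support_in_class)
    rows$strong <- tibble::tibble(
      family = "strong",
      label = vapply(strong$items, paste, character(1), collapse = ","),
      support_adherent = s1, support_non_adherent = s2
    )
  }
  if (nrow(m1) > 0) {
    rows$m1 <- tibble::tibble(
      family = "M1",
      label = vapply(m1$items, paste, character(1), collapse = ","),
      support_adherent = m1$support_c1, support_non_adherent = m1$support_c2
    )
  }
  dat <- dplyr::bind_rows(rows)
  if (nrow(dat) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "Contrast report (no itemsets)") +
             ggplot2::theme_minimal())
  }
  dat <- dat |>
    dplyr::group_by(.data$family) |>
    dplyr::slice_head(n = max_items) |>
    dplyr::ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$support_non_adherent, xend = .data$support_adherent,
      yend = .data$label
    ), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$support_adherent,
                                     colour = "adherent")) +
    ggplot2::geom_point(ggplot2::aes(x = .data$support_non_adherent,
                                     colour = "non_adherent")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$family),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "support", y = NULL, colour = "class",
                  title = "Class-discriminating itemsets") +
    ggplot2::theme_minimal()
}

#' Forest plot of odds ratios for an adherence fit
#'
#' Odds ratios with 95% Wald intervals on a log scale, intercept excluded.
#'
#' @param object An `adherence_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.adherence_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_low,
                                         xmax = .data$or_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL,
                  title = "Adherence odds ratios") +
    ggplot2::theme_minimal()
}
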