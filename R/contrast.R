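#' Confidence of the class-association rule itemset -> class
#'
#' For a two-class dataset the confidence of `{items} -> class` is the
#' fraction of all records containing the itemset that belong to that class,
#' so `confidence(-> adherent) + confidence(-> non_adherent) = 1` for any
#' contained itemset. An itemset contained in no record has undefined
#' confidence and raises an error.
#'
#' @param transactions A `crcs_transactions` object.
#' @param items Integer vector of item codes.
#' @param class_label `"adherent"` or `"non_adherent"`.
#' @return A fraction in `[0, 1]`.
#' @export
rule_confidence <- function(transactions, items, class_label) {
  check_class_label(class_label)
  items <- sort(as.integer(items))
  contains <- vapply(transactions$items, function(r) all(items %in% r),
                     logical(1))
  total <- sum(contains)
  if (total == 0) {
    abort("itemset is contained in no record; confidence is undefined")
  }
  sum(contains & transactions$class == class_label) / total
}

order_by_key <- function(tbl, primary_desc, items_col = "items") {
  keys <- itemset_key(tbl[[items_col]])
  tbl[order(-primary_desc, keys, method = "radix"), , drop = FALSE]
}

## Cross-class support lookup for a list of itemsets.
supports_in_class <- function(transactions, itemsets, class_label) {
  vapply(itemsets, itemset_support, numeric(1),
         transactions = transactions, class_label = class_label)
}

#' Strong class itemsets: high support in one class, low in the other
#'
#' Flags itemsets with support at least `high` (default 80%) in the target
#' class that do not appear in the other class with support at or above
#' `low` (default 60%, i.e. other-class support strictly below 0.6).
#' Candidates are maximal-filtered so only the largest strong combinations
#' are reported, and each carries the rule confidence toward its class.
#'
#' @param transactions A `crcs_transactions` object.
#' @param high Support threshold in the target class (default 0.8).
#' @param low Other-class support must be strictly below this (default 0.6).
#' @return A tibble of class `crcs_strong` with columns `class`, `items`,
#'   `support_in_class`, `support_in_other`, `confidence`, ordered by class,
#'   then descending in-class support, ties broken lexicographically.
#' @export
strong_itemsets <- function(transactions, high = 0.8, low = 0.6) {
  if (high < low) abort("`high` must be at least `low`")
  per_class <- lapply(CLASS_LEVELS, function(cl) {
    tab <- apriori_itemsets(transactions, cl, min_support = high)
    if (nrow(tab) == 0) {
      return(tibble::tibble(
        class = factor(character(), levels = CLASS_LEVELS),
        items = list(), support_in_class = numeric(),
        support_in_other = numeric(), confidence = numeric()
      ))
    }
    other <- other_class(cl)
    s_other <- supports_in_class(transactions, tab$items, other)
    keep <- s_other < low - 1e-12
    tab <- tab[keep, , drop = FALSE]
    s_other <- s_other[keep]
    if (nrow(tab) > 0) {
      # the strong selection is not downward-closed: pairwise scan
      mx <- maximal_itemsets(tab, assume_closed = FALSE)
      sel <- itemset_key(tab$items) %in% itemset_key(mx$items)
      tab <- tab[sel, , drop = FALSE]
      s_other <- s_other[sel]
    }
    conf <- vapply(tab$items, rule_confidence, numeric(1),
                   transactions = transactions, class_label = cl)
    out <- tibble::tibble(
      class = factor(cl, levels = CLASS_LEVELS)[rep(1, nrow(tab))],
      items = tab$items,
      support_in_class = tab$support,
      support_in_other = s_other,
      confidence = conf
    )
    order_by_key(out, out$support_in_class)
  })
  out <- dplyr::bind_rows(per_class)
  attr(out, "high") <- high
  attr(out, "low") <- low
  class(out) <- c("crcs_strong", class(out))
  out
}

#' M1 contrast: shared frequent itemsets with a large support gap
#'
#' Itemsets frequent (support >= `min_support`) in *both* classes whose
#' absolute support difference is at least `min_diff` (default 20 percentage
#' points). An itemset frequent in only one class never qualifies, however
#' large the gap.
#'
#' @param transactions A `crcs_transactions` object.
#' @param min_support Mining threshold for both classes (default 0.6).
#' @param min_diff Minimum absolute (percentage-point) support difference
#'   (default 0.20).
#' @return A tibble of class `crcs_m1` with columns `items`, `support_c1`
#'   (adherent), `support_c2` (non-adherent), `diff`, sorted by descending
#'   difference, ties broken lexicographically.
#' @export
m1_itemsets <- function(transactions, min_support = 0.6, min_diff = 0.20) {
  t1 <- apriori_itemsets(transactions, "adherent", min_support)
  t2 <- apriori_itemsets(transactions, "non_adherent", min_support)
  k1 <- itemset_key(t1$items)
  k2 <- itemset_key(t2$items)
  shared <- intersect(k1, k2)
  i1 <- match(shared, k1)
  i2 <- match(shared, k2)
  d <- abs(t1$support[i1] - t2$support[i2])
  keep <- d >= min_diff - 1e-12
  out <- tibble::tibble(
    items = t1$items[i1][keep],
    support_c1 = t1$support[i1][keep],
    support_c2 = t2$support[i2][keep],
    diff = d[keep]
  )
  out <- order_by_key(out, out$diff)
  attr(out, "min_support") <- min_support
  attr(out, "min_diff") <- min_diff
  class(out) <- c("crcs_m1", class(out))
  out
}

#' M2 contrast: class-unique extensions of subsets shared across classes
#'
#' For each itemset `S` frequent in exactly one class, finds the non-empty
#' proper subsets `B` of `S` that are frequent in *both* classes and reports
#' the pair (shared subset `B`, extension `S \\ B`): attributes strongly
#' shared between groups that become class-specific once the extension items
#' are added. By default only the maximal qualifying subsets of each `S` are
#' reported (every sub-subset of a qualifying `B` also qualifies, which would
#' flood the output); set `all_subsets = TRUE` for the full list. An empty
#' result for a class is a legal outcome.
#'
#' @param transactions A `crcs_transactions` object.
#' @param min_support Mining threshold for both classes (default 0.6).
#' @param all_subsets Report every qualifying shared subset, not just
#'   maximal ones.
#' @return A tibble of class `crcs_m2` with columns `class` (the class where
#'   the full itemset is frequent), `shared_subset`, `extension`,
#'   `subset_support_c1`, `subset_support_c2`, `superset_support_in_class`,
#'   `superset_support_in_other`, ordered by class then descending superset
#'   support, ties broken lexicographically.
#' @export
m2_itemsets <- function(transactions, min_support = 0.6, all_subsets = FALSE) {
  t1 <- apriori_itemsets(transactions, "adherent", min_support)
  t2 <- apriori_itemsets(transactions, "non_adherent", min_support)
  k1 <- itemset_key(t1$items)
  k2 <- itemset_key(t2$items)
  both <- intersect(k1, k2)

  ## subset supports can be read off the mined tables (B is frequent in both);
  ## only the class-unique superset's support in the *other* class needs
  ## counting, done in one incidence-matrix pass per class.
  s1_of <- function(keys_wanted) t1$support[match(keys_wanted, k1)]
  s2_of <- function(keys_wanted) t2$support[match(keys_wanted, k2)]

  batch_other_support <- function(itemsets, cl) {
    if (length(itemsets) == 0) return(numeric(0))
    recs <- class_records(transactions, other_class(cl))
    universe <- sort(unique(unlist(itemsets)))
    M <- incidence_matrix(recs, universe)
    storage.mode(M) <- "integer"
    sizes <- lengths(itemsets)
    C <- matrix(0L, nrow = length(universe), ncol = length(itemsets))
    C[cbind(match(unlist(itemsets), universe),
            rep(seq_along(itemsets), sizes))] <- 1L
    colSums((M %*% C) == rep(sizes, each = length(recs))) / length(recs)
  }

  one_class <- function(tab, keys, cl) {
    unique_idx <- which(!keys %in% both)
    other_support <- rep(NA_real_, nrow(tab))
    other_support[unique_idx] <-
      batch_other_support(tab$items[unique_idx], cl)
    rows <- list()
    for (i in unique_idx) {
      S <- tab$items[[i]]
      if (length(S) < 2) next  # no non-empty proper subset
      subs <- proper_subsets(S)
      qual <- subs[itemset_key(subs) %in% both]
      if (length(qual) == 0) next
      if (!all_subsets && length(qual) > 1) {
        sizes <- lengths(qual)
        keep <- vapply(seq_along(qual), function(a) {
          !any(vapply(seq_along(qual), function(b) {
            sizes[b] > sizes[a] && all(qual[[a]] %in% qual[[b]])
          }, logical(1)))
        }, logical(1))
        qual <- qual[keep]
      }
      qkeys <- itemset_key(qual)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        class = factor(cl, levels = CLASS_LEVELS),
        shared_subset = qual,
        extension = lapply(qual, function(B) setdiff(S, B)),
        subset_support_c1 = s1_of(qkeys),
        subset_support_c2 = s2_of(qkeys),
        superset_support_in_class = tab$support[i],
        superset_support_in_other = other_support[i]
      )
    }
    dplyr::bind_rows(rows)
  }

  out <- dplyr::bind_rows(
    one_class(t1, k1, "adherent"),
    one_class(t2, k2, "non_adherent")
  )
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      class = factor(character(), levels = CLASS_LEVELS),
      shared_subset = list(), extension = list(),
      subset_support_c1 = numeric(), subset_support_c2 = numeric(),
      superset_support_in_class = numeric(),
      superset_support_in_other = numeric()
    )
  } else {
    keys <- paste(itemset_key(out$shared_subset),
                  itemset_key(out$extension), sep = " + ")
    out <- out[order(out$class, -out$superset_support_in_class, keys,
                     method = "radix"), , drop = FALSE]
  }
  attr(out, "min_support") <- min_support
  class(out) <- c("crcs_m2", class(out))
  out
}

## All non-empty proper subsets of a (short) itemset.
proper_subsets <- function(S) {
  m <- length(S)
  if (m < 2) return(list())
  out <- list()
  for (k in seq_len(m - 1)) {
    combos <- utils::combn(S, k, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Full contrast report: strong itemsets, M1 and M2
#'
#' Runs all three contrast extractions at shared parameters and bundles the
#' results with the thresholds used.
#'
#' @param transactions A `crcs_transactions` object.
#' @param min_support Mining threshold (default 0.6).
#' @param strong_high,strong_low Strong-itemset thresholds (defaults 0.8 and
#'   0.6).
#' @param m1_diff Minimum M1 support difference (default 0.20).
#' @param all_subsets Passed to [m2_itemsets()].
#' @return A list of class `contrast_report` with elements `strong`, `m1`,
#'   `m2` and `params`.
#' @export
contrast_report <- function(transactions, min_support = 0.6,
                            strong_high = 0.8, strong_low = 0.6,
                            m1_diff = 0.20, all_subsets = FALSE) {
  out <- list(
    strong = strong_itemsets(transactions, strong_high, strong_low),
    m1 = m1_itemsets(transactions, min_support, m1_diff),
    m2 = m2_itemsets(transactions, min_support, all_subsets = all_subsets),
    params = list(
      min_support = min_support, strong_high = strong_high,
      strong_low = strong_low, m1_diff = m1_diff
    )
  )
  class(out) <- "contrast_report"
  out
}

#' @export
print.contrast_report <- function(x, ...) {
  cat("Contrast report (min_support =", x$params$min_support,
      ", strong >=", x$params$strong_high, "vs <", x$params$strong_low,
      ", M1 diff >=", x$params$m1_diff, ")\n")
  cat("  strong itemsets:", sum(x$strong$class == "adherent"), "adherent,",
      sum(x$strong$class == "non_adherent"), "non-adherent\n")
  cat("  M1 shared itemsets with large gap:", nrow(x$m1), "\n")
  cat("  M2 shared-subset/extension pairs:", nrow(x$m2), "\n")
  invisible(x)
}

#' Write a contrast report to disk
#'
#' Emits a JSON file with all three rule families and a TSV per family with
#' decoded item labels when a codebook is supplied.
#'
#' @param report A [contrast_report()] object.
#' @param dir Output directory (created if needed).
#' @param codebook Optional codebook for decoded labels.
#' @return The directory, invisibly.
#' @export
write_contrast_report <- function(report, dir, codebook = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lab <- function(itemsets) {
    if (is.null(codebook)) {
      vapply(itemsets, paste, character(1), collapse = ",")
    } else {
      vapply(itemsets, format_itemset, character(1), codebook = codebook)
    }
  }
  strong_flat <- dplyr::mutate(tibble::as_tibble(report$strong),
                               items = lab(.data$items))
  m1_flat <- dplyr::mutate(tibble::as_tibble(report$m1),
                           items = lab(.data$items))
  m2_flat <- dplyr::mutate(tibble::as_tibble(report$m2),
                           shared_subset = lab(.data$shared_subset),
                           extension = lab(.data$extension))
  readr::write_tsv(strong_flat, file.path(dir, "strong_itemsets.tsv"))
  readr::write_tsv(m1_flat, file.path(dir, "m1_itemsets.tsv"))
  readr::write_tsv(m2_flat, file.path(dir, "m2_itemsets.tsv"))
  jsonlite::write_json(
    list(
      params = report$params,
      strong = tibble::as_tibble(report$strong),
      m1 = tibble::as_tibble(report$m1),
      m2 = tibble::as_tibble(report$m2)
    ),
    file.path(dir, "contrast_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
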