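## Frequency is decided on counts, not floating-point fractions: an itemset is
## frequent iff its containment count >= ceiling(min_support * n), with a tiny
## guard so that e.g. 0.6 * 411 (not integral) and 0.5 * 4 (integral) both
## round to the exact rational threshold.
support_count_threshold <- function(min_support, n) {
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    abort("`min_support` must be in (0, 1]")
  }
  as.integer(ceiling(min_support * n - 1e-9))
}

itemset_key <- function(items) {
  vapply(items, function(x) paste(x, collapse = "|"), character(1))
}

#' Support of an itemset within one adherence class
#'
#' The support of an itemset in a class is the fraction of that class's
#' records whose item set contains it. The empty itemset has support 1.
#'
#' @param transactions A `crcs_transactions` object.
#' @param items Integer vector of item codes (may be empty).
#' @param class_label `"adherent"` or `"non_adherent"`.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' tx <- as_transactions(
#'   list(c(1001, 2002), c(1001, 2002), c(1001, 2002), c(1001), c(3001)),
#'   class = "adherent"
#' )
#' itemset_support(tx, c(1001, 2002), "adherent")  # 0.6
itemset_support <- function(transactions, items, class_label) {
  recs <- class_records(transactions, class_label)
  items <- sort(as.integer(items))
  if (length(items) == 0) return(1)
  mean(vapply(recs, function(r) all(items %in% r), logical(1)))
}

## Incidence matrix of the class's records over a fixed item universe.
incidence_matrix <- function(recs, universe) {
  n <- length(recs)
  M <- matrix(FALSE, nrow = n, ncol = length(universe))
  if (length(universe) > 0 && n > 0) {
    rows <- rep(seq_len(n), lengths(recs))
    idx <- match(unlist(recs), universe)
    keep <- !is.na(idx)
    M[cbind(rows[keep], idx[keep])] <- TRUE
  }
  M
}

freq_table <- function(itemsets, counts, n, class_label, min_support) {
  supports <- counts / n
  sizes <- lengths(itemsets)
  keys <- itemset_key(itemsets)
  ord <- order(sizes, keys, method = "radix")
  out <- tibble::tibble(
    items = itemsets[ord],
    size = sizes[ord],
    support = supports[ord],
    count = as.integer(counts[ord])
  )
  attr(out, "class_label") <- class_label
  attr(out, "min_support") <- min_support
  attr(out, "n") <- n
  attr(out, "closed") <- TRUE   # table satisfies downward closure
  class(out) <- c("crcs_itemsets", setdiff(class(out), "crcs_itemsets"))
  out
}

#' Per-class frequent itemsets via the Apriori algorithm
#'
#' Level-wise search for all question-disjoint itemsets whose support within
#' the given class is at least `min_support` (inclusive: an itemset occurring
#' in exactly 60% of class records is frequent at threshold 0.6). Candidates
#' of size k are generated by joining size-(k-1) itemsets sharing a (k-2)
#' prefix, discarding joins whose two new items come from the same question
#' (two options of one question never co-occur) and pruning candidates with
#' an infrequent (k-1)-subset. The empty itemset is excluded; singletons are
#' included. Output order is deterministic: by itemset size, then
#' lexicographically by item codes.
#'
#' @param transactions A `crcs_transactions` object.
#' @param class_label `"adherent"` or `"non_adherent"`.
#' @param min_support Minimum support fraction in (0, 1]. Default 0.6, the
#'   threshold at which an itemset must occur in at least 60% of the class's
#'   records.
#' @param max_itemsets Guard on the total number of frequent itemsets
#'   (default 1e6). Low thresholds on wide surveys are combinatorially
#'   explosive; exceeding the guard raises an error suggesting a higher
#'   threshold instead of exhausting memory.
#' @return A tibble of class `crcs_itemsets` with columns `items`
#'   (list-column of sorted item codes), `size`, `support`, `count`, and
#'   attributes `class_label`, `min_support`, `n` (class size).
#' @export
apriori_itemsets <- function(transactions, class_label, min_support = 0.6,
                             max_itemsets = 1e6) {
  recs <- class_records(transactions, class_label)
  n <- length(recs)
  min_count <- support_count_threshold(min_support, n)

  all_codes <- unlist(recs)
  counts1 <- table(all_codes)
  freq1 <- sort(as.integer(names(counts1)[counts1 >= min_count]))
  if (length(freq1) == 0) {
    return(freq_table(list(), integer(0), n, class_label, min_support))
  }
  M <- incidence_matrix(recs, freq1)
  storage.mode(M) <- "integer"
  questions <- item_question(freq1)

  level_sets <- list(as.list(seq_along(freq1)))  # column-index itemsets
  level_counts <- list(as.integer(counts1[as.character(freq1)]))

  k <- 1L
  repeat {
    prev <- level_sets[[k]]
    if (length(prev) < 2) break
    prev_keys <- new.env(parent = emptyenv())
    for (key in itemset_key(prev)) assign(key, TRUE, envir = prev_keys)

    # group by (k-1)-prefix for the classic join
    prefixes <- vapply(prev, function(x) paste(x[-length(x)], collapse = "|"),
                       character(1))
    groups <- split(seq_along(prev), prefixes)
    cands <- list()
    for (g in groups) {
      if (length(cands) > max_itemsets) {
        abort(paste0(
          "candidate explosion at support ", min_support, " (over ",
          format(max_itemsets, scientific = FALSE),
          " size-", k + 1, " candidates); raise the threshold (or `max_itemsets`)"
        ))
      }
      if (length(g) < 2) next
      lasts <- vapply(prev[g], function(x) x[length(x)], integer(1))
      o <- order(lasts)
      g <- g[o]; lasts <- lasts[o]
      for (a in seq_len(length(g) - 1)) {
        for (b in seq((a + 1), length(g))) {
          if (questions[lasts[a]] == questions[lasts[b]]) next
          cand <- c(prev[[g[a]]], lasts[b])
          # prune: every k-subset must be frequent
          ok <- TRUE
          if (k >= 2) {
            for (drop in seq_len(k - 1)) {  # dropping last two covered by parents
              sub <- cand[-drop]
              if (!exists(paste(sub, collapse = "|"), envir = prev_keys)) {
                ok <- FALSE
                break
              }
            }
          }
          if (ok) cands[[length(cands) + 1L]] <- cand
        }
      }
    }
    if (length(cands) == 0) break
    counts <- colSums((M %*% {
      C <- matrix(0L, nrow = ncol(M), ncol = length(cands))
      C[cbind(unlist(cands), rep(seq_along(cands), lengths(cands)))] <- 1L
      C
    }) == (k + 1L))
    keep <- counts >= min_count
    if (!any(keep)) break
    level_sets[[k + 1L]] <- cands[keep]
    level_counts[[k + 1L]] <- as.integer(counts[keep])
    if (sum(lengths(level_sets)) > max_itemsets) {
      abort(paste0(
        "more than ", format(max_itemsets, scientific = FALSE),
        " frequent itemsets at support ", min_support,
        "; raise the threshold (or `max_itemsets`)"
      ))
    }
    k <- k + 1L
  }

  itemsets <- lapply(unlist(level_sets, recursive = FALSE),
                     function(idx) freq1[idx])
  freq_table(itemsets, unlist(level_counts), n, class_label, min_support)
}

#' Keep only maximal (maximum-superset) frequent itemsets
#'
#' A frequent itemset is maximal when no proper frequent superset exists in
#' the same table; filtering to maximal itemsets removes every entry that is
#' implied by a larger one, leaving an antichain under set inclusion.
#' Supports are unchanged.
#'
#' @param table A `crcs_itemsets` table (satisfying downward closure).
#' @param keep_all If `TRUE`, return all entries with an `is_maximal` flag
#'   instead of dropping non-maximal ones.
#' @param assume_closed Use the linear-time subset-marking algorithm, which
#'   is only valid when the table satisfies downward closure (every subset
#'   of an entry is also an entry). Defaults to the table's own `closed`
#'   attribute, set by [apriori_itemsets()] and [brute_force_itemsets()];
#'   arbitrary tables fall back to a pairwise containment scan.
#' @return A `crcs_itemsets` tibble with an `is_maximal` logical column.
#' @export
maximal_itemsets <- function(table, keep_all = FALSE, assume_closed = NULL) {
  m <- nrow(table)
  is_max <- rep(TRUE, m)
  assume_closed <- assume_closed %||% isTRUE(attr(table, "closed"))
  if (m > 1 && assume_closed) {
    # under downward closure an entry is non-maximal iff it is a
    # (size-1)-subset of some entry: mark those subsets of every itemset
    marked <- new.env(parent = emptyenv())
    for (s in table$items) {
      if (length(s) >= 2) {
        for (drop in seq_along(s)) {
          assign(paste(s[-drop], collapse = "|"), TRUE, envir = marked)
        }
      }
    }
    keys <- itemset_key(table$items)
    is_max <- !vapply(keys, exists, logical(1), envir = marked,
                      USE.NAMES = FALSE)
  } else if (m > 1) {
    sizes <- table$size
    universe <- sort(unique(unlist(table$items)))
    A <- matrix(0L, nrow = m, ncol = length(universe))
    A[cbind(rep(seq_len(m), sizes), match(unlist(table$items), universe))] <- 1L
    inter <- tcrossprod(A)        # inter[i, j] = |items_i intersect items_j|
    for (i in seq_len(m)) {
      is_max[i] <- !any(inter[i, ] == sizes[i] & sizes > sizes[i])
    }
  }
  out <- table
  out$is_maximal <- is_max
  if (!keep_all) out <- out[is_max, , drop = FALSE]
  for (a in c("class_label", "min_support", "n")) {
    attr(out, a) <- attr(table, a)
  }
  class(out) <- c("crcs_itemsets", setdiff(class(out), "crcs_itemsets"))
  out
}

#' Exhaustive frequent-itemset enumeration (small-universe oracle)
#'
#' Enumerates every non-empty question-disjoint subset of the class's item
#' universe and keeps those meeting the support threshold. Exponential in the
#' number of distinct items, so guarded to at most `max_items`; intended as
#' an independent check of [apriori_itemsets()] on small instances.
#'
#' @inheritParams apriori_itemsets
#' @param max_items Guard on the number of distinct items (default 16).
#' @return A `crcs_itemsets` tibble identical in form to
#'   [apriori_itemsets()] output.
#' @export
brute_force_itemsets <- function(transactions, class_label, min_support,
                                 max_items = 16L) {
  recs <- class_records(transactions, class_label)
  n <- length(recs)
  min_count <- support_count_threshold(min_support, n)
  universe <- sort(unique(unlist(recs)))
  m <- length(universe)
  if (m > max_items) {
    abort(paste0("item universe has ", m, " items; oracle guard is ", max_items))
  }
  if (m == 0) {
    return(freq_table(list(), integer(0), n, class_label, min_support))
  }
  questions <- item_question(universe)
  masks <- seq_len(2^m - 1)
  bit <- function(mask, j) bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0
  member <- vapply(seq_len(m), function(j) bit(masks, j), logical(length(masks)))
  member <- matrix(member, nrow = length(masks))
  # question-disjoint subsets only
  disjoint <- vapply(seq_len(nrow(member)), function(i) {
    !anyDuplicated(questions[member[i, ]])
  }, logical(1))
  member <- member[disjoint, , drop = FALSE]
  M <- incidence_matrix(recs, universe)
  storage.mode(M) <- "integer"
  sizes <- rowSums(member)
  counts <- colSums((M %*% t(member * 1L)) == rep(sizes, each = n))
  keep <- counts >= min_count
  itemsets <- lapply(which(keep), function(i) universe[member[i, ]])
  freq_table(itemsets, as.integer(counts[keep]), n, class_label, min_support)
}

#' Frequent-itemset counts across a grid of support thresholds
#'
#' Re-mines each class at every threshold and reports how many frequent and
#' maximal itemsets survive: the exploratory sweep used to pick a working
#' support threshold (counts are non-increasing in the threshold).
#'
#' @param transactions A `crcs_transactions` object.
#' @param thresholds Numeric vector of thresholds in (0, 1]; default the 10%
#'   grid `seq(0.1, 1, by = 0.1)`.
#' @return A tibble of class `crcs_sweep` with columns `threshold`, `class`,
#'   `n_frequent`, `n_maximal`.
#' @export
support_sweep <- function(transactions, thresholds = seq(0.1, 1, by = 0.1)) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("`thresholds` must lie in (0, 1]")
  }
  grid <- tidyr::expand_grid(
    threshold = thresholds,
    class = factor(CLASS_LEVELS, levels = CLASS_LEVELS)
  )
  res <- purrr::pmap(grid, function(threshold, class) {
    tab <- apriori_itemsets(transactions, as.character(class), threshold)
    tibble::tibble(
      n_frequent = nrow(tab),
      n_maximal = nrow(maximal_itemsets(tab))
    )
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  class(out) <- c("crcs_sweep", class(out))
  out
}

#' Write a frequent-itemset table as TSV
#'
#' One row per itemset with codes, decoded labels (when a codebook is
#' given), support and maximal flag.
#'
#' @param table A `crcs_itemsets` table (optionally from
#'   [maximal_itemsets()] with `keep_all = TRUE`).
#' @param path Output path.
#' @param codebook Optional codebook for decoded labels.
#' @return `path`, invisibly.
#' @export
write_itemsets <- function(table, path, codebook = NULL) {
  flat <- tibble::tibble(
    class = attr(table, "class_label") %||% NA_character_,
    items = vapply(table$items, paste, character(1), collapse = ","),
    labels = if (is.null(codebook)) NA_character_ else
      vapply(table$items, format_itemset, character(1), codebook = codebook),
    size = table$size,
    support = table$support,
    is_maximal = if ("is_maximal" %in% names(table)) table$is_maximal else NA
  )
  readr::write_tsv(flat, path)
  invisible(path)
}
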