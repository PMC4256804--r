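# Independent brute-force oracles, deliberately written as plain
# filter-by-definition comprehensions so they share no code with the
# package's level-wise implementation.

# All frequent question-disjoint itemsets by exhaustive enumeration.
oracle_frequent <- function(recs, min_support) {
  n <- length(recs)
  universe <- sort(unique(unlist(recs)))
  L <- sapply(universe, function(it)
    sapply(recs, function(r) it %in% r))
  L <- matrix(L, nrow = n)
  out_items <- list()
  out_support <- numeric()
  for (k in seq_along(universe)) {
    for (cand in utils::combn(seq_along(universe), k, simplify = FALSE)) {
      codes <- universe[cand]
      if (anyDuplicated(codes %/% 1000)) next
      cnt <- sum(rowSums(L[, cand, drop = FALSE]) == k)
      if (cnt >= min_support * n - 1e-9) {
        out_items[[length(out_items) + 1L]] <- codes
        out_support[length(out_support) + 1L] <- cnt / n
      }
    }
  }
  list(items = out_items, support = out_support)
}

# type-stable itemset keys (empty list -> character(0))
keys_of <- function(items) {
  vapply(items, paste, character(1), collapse = "|")
}

oracle_key <- function(items) {
  vapply(items, function(x) paste(sort(x), collapse = "|"), character(1))
}

# Maximal entries by pairwise definition scan.
oracle_maximal <- function(items) {
  m <- length(items)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j && length(items[[i]]) < length(items[[j]]) &&
          all(items[[i]] %in% items[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

oracle_support <- function(recs, codes) {
  mean(sapply(recs, function(r) all(codes %in% r)))
}

# M1 by direct comprehension over two oracle tables.
oracle_m1 <- function(f1, f2, min_diff) {
  k1 <- oracle_key(f1$items)
  k2 <- oracle_key(f2$items)
  shared <- intersect(k1, k2)
  res <- list()
  for (key in shared) {
    s1 <- f1$support[match(key, k1)]
    s2 <- f2$support[match(key, k2)]
    if (abs(s1 - s2) >= min_diff - 1e-12) {
      res[[length(res) + 1L]] <- list(
        items = f1$items[[match(key, k1)]], s1 = s1, s2 = s2
      )
    }
  }
  res
}

# All M2 pairs (every qualifying shared subset, not just maximal ones).
oracle_m2_all <- function(f1, f2) {
  k1 <- oracle_key(f1$items)
  k2 <- oracle_key(f2$items)
  both <- intersect(k1, k2)
  res <- list()
  emit <- function(S, cl) {
    m <- length(S)
    if (m < 2) return()
    for (k in seq_len(m - 1)) {
      for (B in utils::combn(S, k, simplify = FALSE)) {
        if (oracle_key(list(B)) %in% both) {
          res[[length(res) + 1L]] <<- list(
            class = cl, shared = sort(B), ext = sort(setdiff(S, B))
          )
        }
      }
    }
  }
  for (i in which(!k1 %in% both)) emit(f1$items[[i]], "adherent")
  for (i in which(!k2 %in% both)) emit(f2$items[[i]], "non_adherent")
  res
}

# Strong itemsets by definition: support >= high in the class, < low in the
# other, then maximal among the qualifying set.
oracle_strong <- function(recs_class, recs_other, high, low) {
  n <- length(recs_class)
  f <- oracle_frequent(recs_class, high)
  qual <- list()
  for (i in seq_along(f$items)) {
    if (oracle_support(recs_other, f$items[[i]]) < low - 1e-12) {
      qual[[length(qual) + 1L]] <- f$items[[i]]
    }
  }
  qual[oracle_maximal(qual)]
}

# Random small class-labelled datasets for oracle-equivalence checks:
# a handful of questions with a few options each, answers drawn at random,
# some questions left unanswered.
random_small_transactions <- function(n_questions = 3, max_options = 4,
                                      n1 = 30, n2 = 25) {
  n_opts <- sample.int(max_options, n_questions, replace = TRUE)
  draw <- function(n) {
    lapply(seq_len(n), function(i) {
      answered <- which(runif(n_questions) < 0.8)
      sort(vapply(answered, function(q) {
        q * 1000L + sample.int(n_opts[q], 1L)
      }, integer(1)))
    })
  }
  as_transactions(c(draw(n1), draw(n2)),
                  class = rep(c("adherent", "non_adherent"), c(n1, n2)))
}

# Small deterministic toy transactions used across contrast tests.
toy_transactions <- function() {
  # C1 (5 recs): {a,b} in 4, {a,b,c} in 2 ; C2 (5 recs): {a,b} in 3
  a <- 1001L; b <- 2001L; c <- 3001L
  as_transactions(
    list(c(a, b, c), c(a, b, c), c(a, b), c(a, b), c(a),
         c(a, b), c(a, b), c(a, b), c(a), c(b)),
    class = rep(c("adherent", "non_adherent"), each = 5)
  )
}
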