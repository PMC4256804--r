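test_that("rule confidence is the class fraction among containing records", {
  # {a,b} contained in 6 adherent and 4 non-adherent records
  a <- 1001L; b <- 2001L
  tx <- as_transactions(
    c(replicate(6, c(a, b), simplify = FALSE), list(c(a)),
      replicate(4, c(a, b), simplify = FALSE), list(c(b))),
    class = rep(c("adherent", "non_adherent"), c(7, 5))
  )
  expect_equal(rule_confidence(tx, c(a, b), "adherent"), 0.6)
  # two-class partition: confidences sum to one
  expect_equal(
    rule_confidence(tx, c(a, b), "adherent") +
      rule_confidence(tx, c(a, b), "non_adherent"),
    1
  )
  # itemset occurring only in one class has confidence 1 toward it
  only_c1 <- as_transactions(
    list(c(a, b), c(a, b), c(b)),
    class = c("adherent", "adherent", "non_adherent")
  )
  expect_equal(rule_confidence(only_c1, c(a, b), "adherent"), 1)
  expect_error(rule_confidence(tx, 99001L, "adherent"), "no record")
})

test_that("strong itemsets need high support in one class and sub-low in the other", {
  a <- 1001L; b <- 2001L
  # {a,b}: 17/20 = 0.85 adherent, 11/20 = 0.55 non-adherent
  tx <- as_transactions(
    c(replicate(17, c(a, b), simplify = FALSE), replicate(3, a, simplify = FALSE),
      replicate(11, c(a, b), simplify = FALSE), replicate(9, b, simplify = FALSE)),
    class = rep(c("adherent", "non_adherent"), each = 20)
  )
  st <- strong_itemsets(tx, high = 0.8, low = 0.6)
  hit <- st[vapply(st$items, identical, logical(1), y = c(a, b)), ]
  expect_equal(nrow(hit), 1)
  expect_equal(as.character(hit$class), "adherent")
  expect_equal(hit$support_in_class, 0.85)
  expect_equal(hit$support_in_other, 0.55)
  expect_equal(hit$confidence, 17 / 28)

  # 0.85 in both classes qualifies for neither side
  tx2 <- as_transactions(
    c(replicate(17, c(a, b), simplify = FALSE), replicate(3, a, simplify = FALSE),
      replicate(17, c(a, b), simplify = FALSE), replicate(3, b, simplify = FALSE)),
    class = rep(c("adherent", "non_adherent"), each = 20)
  )
  st2 <- strong_itemsets(tx2, 0.8, 0.6)
  expect_false(any(vapply(st2$items, identical, logical(1), y = c(a, b))))

  # other-class support exactly at the low bound is excluded (strict <)
  tx3 <- as_transactions(
    c(replicate(17, c(a, b), simplify = FALSE), replicate(3, a, simplify = FALSE),
      replicate(12, c(a, b), simplify = FALSE), replicate(8, b, simplify = FALSE)),
    class = rep(c("adherent", "non_adherent"), each = 20)
  )
  st3 <- strong_itemsets(tx3, 0.8, 0.6)  # 12/20 = 0.60 in the other class
  expect_false(any(vapply(st3$items, identical, logical(1), y = c(a, b))))

  expect_error(strong_itemsets(tx, high = 0.5, low = 0.6), "at least")
})

test_that("M1 needs shared frequency and a 20-point support gap", {
  a <- 1001L
  make_tx <- function(c1_with, c1_n, c2_with, c2_n) {
    as_transactions(
      c(replicate(c1_with, a, simplify = FALSE),
        replicate(c1_n - c1_with, 2001L, simplify = FALSE),
        replicate(c2_with, a, simplify = FALSE),
        replicate(c2_n - c2_with, 2001L, simplify = FALSE)),
      class = rep(c("adherent", "non_adherent"), c(c1_n, c2_n))
    )
  }
  # (0.85, 0.62): included with diff 0.23
  m1 <- m1_itemsets(make_tx(85, 100, 62, 100), 0.6, 0.20)
  hit <- m1[vapply(m1$items, identical, logical(1), y = a), ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$diff, 0.23)
  # (0.70, 0.65): gap too small
  m1b <- m1_itemsets(make_tx(70, 100, 65, 100), 0.6, 0.20)
  expect_false(any(vapply(m1b$items, identical, logical(1), y = a)))
  # (0.85, 0.55): big gap but not frequent in the second class -> excluded
  m1c <- m1_itemsets(make_tx(85, 100, 55, 100), 0.6, 0.20)
  expect_false(any(vapply(m1c$items, identical, logical(1), y = a)))
  # gap of exactly 20 points is included (inclusive >=)
  m1d <- m1_itemsets(make_tx(85, 100, 65, 100), 0.6, 0.20)
  expect_true(any(vapply(m1d$items, identical, logical(1), y = a)))
})

test_that("M2 emits shared subsets with class-unique extensions", {
  a <- 1001L; b <- 2001L; c <- 3001L
  # {a,b} frequent in both; {a,b,c} frequent only in adherent class
  tx <- as_transactions(
    c(replicate(7, c(a, b, c), simplify = FALSE),
      replicate(2, c(a, b), simplify = FALSE),
      list(a),
      replicate(7, c(a, b), simplify = FALSE),
      replicate(3, b, simplify = FALSE)),
    class = rep(c("adherent", "non_adherent"), each = 10)
  )
  m2 <- m2_itemsets(tx, 0.6)
  hit <- m2[vapply(seq_len(nrow(m2)), function(i) {
    identical(m2$shared_subset[[i]], c(a, b)) &&
      identical(m2$extension[[i]], c)
  }, logical(1)), ]
  expect_equal(nrow(hit), 1)
  expect_equal(as.character(hit$class), "adherent")
  expect_equal(hit$subset_support_c1, 0.9)
  expect_equal(hit$subset_support_c2, 0.7)
  expect_equal(hit$superset_support_in_class, 0.7)
  # the maximal-subset default suppresses the sub-subset pair ({a}, {b,c})
  expect_false(any(vapply(seq_len(nrow(m2)), function(i) {
    identical(m2$shared_subset[[i]], a) &&
      identical(m2$extension[[i]], c(b, c))
  }, logical(1))))
  all_m2 <- m2_itemsets(tx, 0.6, all_subsets = TRUE)
  expect_true(any(vapply(seq_len(nrow(all_m2)), function(i) {
    identical(all_m2$shared_subset[[i]], a) &&
      identical(all_m2$extension[[i]], c(b, c))
  }, logical(1))))

  # an itemset frequent in both classes contributes nothing
  tx2 <- as_transactions(
    c(replicate(9, c(a, b), simplify = FALSE), list(a),
      replicate(9, c(a, b), simplify = FALSE), list(b)),
    class = rep(c("adherent", "non_adherent"), each = 10)
  )
  expect_equal(nrow(m2_itemsets(tx2, 0.6)), 0)  # emptiness is a legal outcome
})

test_that("contrast extractions match set-comprehension oracles on random data", {
  withr::local_seed(202)
  for (i in 1:25) {
    tx <- random_small_transactions(n_questions = 3, n1 = 20, n2 = 20)
    threshold <- sample(c(0.3, 0.4, 0.5, 0.6), 1)
    recs1 <- tx$items[tx$class == "adherent"]
    recs2 <- tx$items[tx$class == "non_adherent"]
    f1 <- oracle_frequent(recs1, threshold)
    f2 <- oracle_frequent(recs2, threshold)

    m1 <- m1_itemsets(tx, threshold, 0.20)
    want_m1 <- oracle_m1(f1, f2, 0.20)
    expect_setequal(
      keys_of(m1$items),
      vapply(want_m1, function(e) paste(e$items, collapse = "|"), character(1))
    )

    m2 <- m2_itemsets(tx, threshold, all_subsets = TRUE)
    want_m2 <- oracle_m2_all(f1, f2)
    key <- function(cl, sh, ex) paste(cl, paste(sh, collapse = "|"),
                                      paste(ex, collapse = "|"), sep = "&")
    got_keys <- vapply(seq_len(nrow(m2)), function(j) {
      key(as.character(m2$class[j]), m2$shared_subset[[j]], m2$extension[[j]])
    }, character(1))
    want_keys <- vapply(want_m2, function(e) key(e$class, e$shared, e$ext),
                        character(1))
    expect_setequal(got_keys, want_keys)
    # maximal-subset default is a subset of the full list
    m2_max <- m2_itemsets(tx, threshold)
    max_keys <- vapply(seq_len(nrow(m2_max)), function(j) {
      key(as.character(m2_max$class[j]), m2_max$shared_subset[[j]],
          m2_max$extension[[j]])
    }, character(1))
    expect_true(all(max_keys %in% got_keys))

    st <- strong_itemsets(tx, high = 0.6, low = 0.5)
    want_strong_c1 <- oracle_strong(recs1, recs2, 0.6, 0.5)
    got_c1 <- st$items[st$class == "adherent"]
    expect_setequal(keys_of(got_c1),
                    keys_of(want_strong_c1))
  }
})

test_that("M1 is symmetric under class-label swap up to mirrored differences", {
  withr::local_seed(17)
  tx <- random_small_transactions(n_questions = 3, n1 = 25, n2 = 25)
  swapped <- as_transactions(
    tx$items,
    class = ifelse(tx$class == "adherent", "non_adherent", "adherent")
  )
  m1 <- m1_itemsets(tx, 0.4, 0.1)
  m1s <- m1_itemsets(swapped, 0.4, 0.1)
  expect_setequal(keys_of(m1$items),
                  keys_of(m1s$items))
  k <- keys_of(m1$items)
  ks <- keys_of(m1s$items)
  m <- match(k, ks)
  expect_equal(m1$support_c1, m1s$support_c2[m])
  expect_equal(m1$diff, m1s$diff[m])
})

test_that("reported itemsets decode to valid question-option pairs", {
  sim <- simulate_survey(generator_spec(
    n1 = 120L, n2 = 90L, n_questions = 20L,
    plants = default_plants(), seed = 5
  ))
  tx <- encode_responses(sim$survey, sim$codebook)
  rep <- contrast_report(tx)
  all_codes <- unique(unlist(c(rep$strong$items, rep$m1$items,
                               rep$m2$shared_subset, rep$m2$extension)))
  d <- decode_items(all_codes, sim$codebook)
  expect_equal(nrow(d), length(all_codes))
  expect_true(all(d$option_index >= 1 & d$option_index <= 5))
})
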