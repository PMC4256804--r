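fit_toy_2x2 <- function(a, b, c, d) {
  # a = (x=1,y=1), b = (x=1,y=0), c = (x=0,y=1), d = (x=0,y=0)
  dat <- tibble::tibble(
    .outcome = rep(c(1, 0, 1, 0), c(a, b, c, d)),
    x = rep(c(1, 1, 0, 0), c(a, b, c, d))
  )
  fit_adherence_model(dat)
}

test_that("single binary predictor OR equals the 2x2 cross-product ratio", {
  fit <- fit_toy_2x2(30, 10, 20, 25)
  or <- tidy(fit)$odds_ratio[2]
  expect_equal(or, (30 * 25) / (10 * 20), tolerance = 1e-6)
})

test_that("Wald, OR and CI identities hold on every fitted term", {
  withr::local_seed(9)
  d <- simulate_regression_data(400)
  fit <- fit_adherence_model(d)
  td <- tidy(fit)
  expect_equal(td$odds_ratio, exp(td$estimate))
  expect_equal(td$wald, (td$estimate / td$std_error)^2)
  expect_equal(td$or_low, exp(td$estimate - 1.96 * td$std_error))
  expect_equal(td$or_high, exp(td$estimate + 1.96 * td$std_error))
  gl <- glance(fit)
  expect_gte(gl$cox_snell_r2, 0)
  expect_lte(gl$cox_snell_r2, gl$nagelkerke_r2)
  expect_lte(gl$nagelkerke_r2, 1)
})

test_that("pseudo-R2 formulas evaluate exactly from the log-likelihoods", {
  fit <- fit_toy_2x2(6, 2, 3, 5)
  r2 <- pseudo_r2(fit)
  n <- fit$n_used
  want_cox <- 1 - exp(2 * (fit$ll_null - fit$ll_model) / n)
  want_nag <- want_cox / (1 - exp(2 * fit$ll_null / n))
  expect_equal(unname(r2["cox_snell"]), want_cox, tolerance = 1e-10)
  expect_equal(unname(r2["nagelkerke"]), want_nag, tolerance = 1e-10)
})

test_that("an intercept-only-strength predictor gives zero pseudo-R2", {
  # predictor carries no information: fitted model equals the null model
  dat <- tibble::tibble(
    .outcome = rep(c(1, 0, 1, 0), c(10, 10, 10, 10)),
    x = rep(c(1, 1, 0, 0), c(10, 10, 10, 10))
  )
  fit <- fit_adherence_model(dat)
  r2 <- pseudo_r2(fit)
  expect_equal(unname(r2["cox_snell"]), 0, tolerance = 1e-10)
  expect_equal(unname(r2["nagelkerke"]), 0, tolerance = 1e-10)
})

test_that("Hosmer-Lemeshow df tracks the number of covariate patterns", {
  # 7 distinct covariate patterns -> 7 groups -> df = 5
  withr::local_seed(31)
  x <- sample(1:7, 700, replace = TRUE)
  p_true <- plogis(-1 + 0.3 * x)
  d <- tibble::tibble(.outcome = rbinom(700, 1, p_true), x = x)
  fit <- fit_adherence_model(d)
  hl <- hosmer_lemeshow(fit, groups = 10)
  expect_equal(unname(hl["g"]), 7)
  expect_equal(unname(hl["df"]), 5)
  expect_equal(unname(hl["p_value"]),
               pchisq(hl[["chisq"]], 5, lower.tail = FALSE))
})

test_that("Hosmer-Lemeshow is zero for a saturated fit and matches hand counts", {
  # saturated model on a 3-level factor: fitted probabilities equal the
  # observed group rates, so every O - E is zero
  withr::local_seed(77)
  g3 <- sample(1:3, 300, replace = TRUE)
  d <- tibble::tibble(
    .outcome = rbinom(300, 1, c(0.2, 0.5, 0.8)[g3]),
    x1 = as.numeric(g3 == 2),
    x2 = as.numeric(g3 == 3)
  )
  fit <- fit_adherence_model(d)
  hl <- hosmer_lemeshow(fit)
  expect_equal(unname(hl["chisq"]), 0, tolerance = 1e-12)

  # hand-computed chi-square on an unsaturated fit with 5 covariate patterns
  x5 <- sample(1:5, 400, replace = TRUE)
  d5 <- tibble::tibble(.outcome = rbinom(400, 1, plogis(-1 + 0.4 * x5)),
                       x = x5)
  fit2 <- fit_adherence_model(d5)
  hl2 <- hosmer_lemeshow(fit2)
  p <- fitted(fit2$glm)
  y <- fit2$data$.outcome
  chisq_hand <- 0
  for (pp in sort(unique(round(p, 12)))) {
    sel <- abs(p - pp) < 1e-9
    O1 <- sum(y[sel]); E1 <- sum(p[sel])
    O0 <- sum(sel) - O1; E0 <- sum(sel) - E1
    chisq_hand <- chisq_hand + (O1 - E1)^2 / E1 + (O0 - E0)^2 / E0
  }
  expect_equal(unname(hl2["chisq"]), chisq_hand, tolerance = 1e-8)
  expect_error(hosmer_lemeshow(fit_toy_2x2(30, 10, 20, 25)), "fewer than 3")
})

test_that("classification table matches hand-built confusion matrices", {
  # near-perfect predictor (one flip per arm keeps the MLE finite)
  dperf <- tibble::tibble(
    .outcome = rep(c(1, 0, 1, 0), c(19, 1, 1, 19)),
    x = rep(c(1, 1, 0, 0), c(19, 1, 1, 19))
  )
  fit <- fit_adherence_model(dperf)
  ct <- classification_table(fit)
  expect_equal(ct$pct_correct_class0, 95)
  expect_equal(ct$pct_correct_class1, 95)
  expect_equal(ct$pct_correct_overall, 95)

  # constant fitted probability 0.6 with cutoff 0.5: all predicted class 1
  dconst <- tibble::tibble(.outcome = rep(c(1, 0), c(12, 8)),
                           x = rep(0, 20))
  # x is constant -> rank-deficient design is refused; use intercept via a
  # non-informative balanced predictor instead
  dconst$x <- rep(c(1, 0), 10)
  fitc <- fit_adherence_model(dconst)
  ctc <- classification_table(fitc)
  expect_equal(ctc$pct_correct_class1, 100)
  expect_equal(ctc$pct_correct_class0, 0)

  # hand-built 20-record confusion matrix (mixed outcomes in both arms)
  d20 <- tibble::tibble(
    .outcome = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
    x = rep(c(1, 0), each = 10)
  )
  fit20 <- fit_adherence_model(d20)
  p <- fitted(fit20$glm)
  y <- d20$.outcome
  pred <- as.integer(p >= 0.5)
  ct20 <- classification_table(fit20)
  expect_equal(ct20$pct_correct_class1, 100 * sum(pred == 1 & y == 1) / sum(y == 1))
  expect_equal(ct20$pct_correct_class0, 100 * sum(pred == 0 & y == 0) / sum(y == 0))
  expect_equal(ct20$pct_correct_overall, 100 * mean(pred == y))
})

test_that("fit errors name rank-deficient and degenerate designs", {
  d <- tibble::tibble(.outcome = rep(c(1, 0), 10), x = rnorm(20))
  d$x2 <- 2 * d$x
  expect_error(fit_adherence_model(d), "collinear")
  expect_error(
    fit_adherence_model(tibble::tibble(.outcome = rep(1, 10), x = rnorm(10))),
    "single level"
  )
  dsep <- tibble::tibble(.outcome = rep(c(1, 0), each = 10),
                         x = rep(c(1, 0), each = 10))
  expect_error(suppressWarnings(fit_adherence_model(dsep)), "separation")
})

test_that("listwise deletion drops exactly the incomplete records", {
  withr::local_seed(4)
  d <- simulate_regression_data(100)
  d$x1[c(3, 50)] <- NA
  d$.outcome[10] <- NA
  fit <- fit_adherence_model(d)
  expect_equal(fit$n_used, 97)
})

test_that("null predictors rarely reach Wald significance", {
  withr::local_seed(2024)
  n_sig <- 0L
  for (i in 1:100) {
    d <- tibble::tibble(
      .outcome = rbinom(2000, 1, 0.5),
      x = rbinom(2000, 1, 0.5)
    )
    td <- tidy(fit_adherence_model(d))
    if (td$p_value[td$term == "x"] <= 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 10L)  # >= 90% of null fits non-significant
})

test_that("coefficient bias shrinks as the sample grows", {
  withr::local_seed(321)
  scen <- default_regression_scenario()
  sizes <- c(500, 2000, 8000)
  bias <- matrix(0, nrow = 3, ncol = 3,
                 dimnames = list(NULL, names(scen$coefficients)))
  n_seeds <- 50
  for (s in seq_along(sizes)) {
    est <- matrix(0, nrow = n_seeds, ncol = 3)
    for (r in seq_len(n_seeds)) {
      d <- simulate_regression_data(sizes[s], scen)
      est[r, ] <- tidy(fit_adherence_model(d))$estimate[2:4]
    }
    bias[s, ] <- colMeans(est) - scen$coefficients
  }
  for (j in 1:3) {
    steps <- diff(abs(bias[, j]))
    expect_gte(sum(steps < 0), 1)   # |bias| falls in at least 2 of 3 sizes
  }
  expect_lt(max(abs(bias[3, ])), 0.1)
})

test_that("log-likelihood of the fitted model never falls below the null", {
  withr::local_seed(88)
  for (i in 1:5) {
    d <- simulate_regression_data(300)
    fit <- fit_adherence_model(d)
    expect_gte(fit$ll_model, fit$ll_null - 1e-8)
  }
})
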