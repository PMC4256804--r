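#' Default planted itemsets for generator validation
#'
#' Three plants exercising each contrast-rule family at its selection
#' boundary conditions:
#' * a strong-adherent pair (questions 5 and 6) at support 0.85 in the
#'   adherent class and 0.55 in the non-adherent class;
#' * an M1 pair (questions 7 and 8) frequent in both classes (0.85 / 0.62,
#'   a 23-point gap);
#' * an M2 configuration: a shared singleton (question 9) at 0.90 in both
#'   classes whose extension (question 10) is frequent only among adherent
#'   records, so their union is frequent in the adherent class alone.
#'
#' @return A tibble with columns `name`, `questions` (list), `option`,
#'   `support_c1`, `support_c2`, `mode`.
#' @export
default_plants <- function() {
  tibble::tibble(
    name = c("strong_c1", "m1", "m2_shared", "m2_extension"),
    questions = list(c(5L, 6L), c(7L, 8L), 9L, 10L),
    option = 1L,
    support_c1 = c(0.85, 0.85, 0.90, 0.70),
    support_c2 = c(0.55, 0.62, 0.90, 0.30),
    mode = "deterministic"
  )
}

#' Default regression scenario with known coefficients
#'
#' Three binary predictors with true log-odds coefficients (-1.5, 1.5,
#' -0.3) and an intercept equal to `qlogis(0.5967)` so that the marginal
#' outcome rate sits near the 59.67% adherence rate typical of screening
#' surveys of this size.
#'
#' @return A list with `coefficients`, `intercept`, `predictor_prob`.
#' @export
default_regression_scenario <- function() {
  list(
    coefficients = c(x1 = -1.5, x2 = 1.5, x3 = -0.3),
    intercept = qlogis(0.5967),
    predictor_prob = 0.5
  )
}

#' Specify a synthetic survey generator
#'
#' Defaults reproduce the shape of a desk-scale screening-adherence survey:
#' 608 adherent and 411 non-adherent respondents (1019 records), 144
#' categorical questions with 5 options each (720 distinct items), answers
#' independent given class, and identical class-conditional option profiles
#' apart from the planted itemsets. A fraction of questions are "consensus"
#' questions with a dominant option (probability drawn once per question
#' from `consensus_range`), which is what makes multi-item frequent itemsets
#' appear at realistic support levels; the rest spread probability more
#' evenly over the options (dominant probability from `diverse_range`).
#'
#' @param n1,n2 Class sizes (adherent, non-adherent). Defaults 608 and 411.
#' @param n_questions Number of questions (default 144).
#' @param options_per_question Options per question (default 5).
#' @param prop_consensus Fraction of consensus questions (default 0.25).
#' @param consensus_range,diverse_range Ranges for the dominant-option
#'   probability of the two question types. The consensus upper bound stays
#'   below 0.9 so that background items cannot push a planted itemset's
#'   supersets over the strong-itemset threshold.
#' @param plants Plant table as in [default_plants()], or an empty/`NULL`
#'   table for a null configuration. A question may appear in at most one
#'   plant.
#' @param regression Regression scenario as in
#'   [default_regression_scenario()], or `NULL`.
#' @param seed Integer seed; every random draw flows through it.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n1 = 608L, n2 = 411L, n_questions = 144L,
                           options_per_question = 5L,
                           prop_consensus = 0.25,
                           consensus_range = c(0.70, 0.88),
                           diverse_range = c(0.25, 0.50),
                           plants = default_plants(),
                           regression = default_regression_scenario(),
                           seed = 1L) {
  if (n1 < 1 || n2 < 1) abort("class sizes must be at least 1")
  if (is.null(plants)) {
    plants <- default_plants()[0, ]
  }
  if (nrow(plants) > 0) {
    qs <- unlist(plants$questions)
    if (anyDuplicated(qs)) {
      abort(paste0("conflicting plants: question(s) ",
                   paste(unique(qs[duplicated(qs)]), collapse = ", "),
                   " planted more than once"))
    }
    if (any(qs > n_questions)) abort("planted question beyond n_questions")
    s <- c(plants$support_c1, plants$support_c2)
    if (any(s < 0 | s > 1)) abort("plant target supports must be in [0, 1]")
  }
  structure(
    list(
      n1 = as.integer(n1), n2 = as.integer(n2),
      n_questions = as.integer(n_questions),
      options_per_question = as.integer(options_per_question),
      prop_consensus = prop_consensus,
      consensus_range = consensus_range,
      diverse_range = diverse_range,
      plants = plants,
      regression = regression,
      seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

#' Generate a synthetic class-labelled survey
#'
#' Draws each question's answer independently from its class profile, then
#' applies the plants. A deterministic plant with target support `s` in a
#' class of size `n` overwrites the planted questions' answers in a
#' contiguous slice of exactly `ceiling(s * n)` records, and removes the
#' planted option from every record outside the slice, so the realized
#' support is exactly `ceiling(s * n) / n`. Each plant's slice starts at a
#' distinct evenly spaced offset (wrapping cyclically), so independent
#' plants do not co-occur as an artificial super-itemset. Stochastic plants
#' instead include each record in the plant with probability `s`. The same
#' seed always yields byte-identical tables.
#'
#' @param spec A [generator_spec()].
#' @return A list of class `crcs_simulation`: `survey` (raw table with
#'   `participant_id`, `adherence`, and `Q1..Qn` label columns), `codebook`,
#'   and `truth` (realized per-class plant supports and the regression
#'   scenario).
#' @export
simulate_survey <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  nq <- spec$n_questions
  nopt <- spec$options_per_question
  opt_labels <- paste0("option_", seq_len(nopt))

  codebook <- build_codebook(tibble::tibble(
    question_id = seq_len(nq),
    question_text = sprintf("Survey question %d", seq_len(nq)),
    options = rep(list(opt_labels), nq)
  ))

  # one shared profile per question (classes differ only through plants)
  is_consensus <- runif(nq) < spec$prop_consensus
  dom_prob <- ifelse(
    is_consensus,
    runif(nq, spec$consensus_range[1], spec$consensus_range[2]),
    runif(nq, spec$diverse_range[1], spec$diverse_range[2])
  )
  dom_opt <- sample.int(nopt, nq, replace = TRUE)
  profiles <- lapply(seq_len(nq), function(q) {
    p <- rep((1 - dom_prob[q]) / (nopt - 1), nopt)
    p[dom_opt[q]] <- dom_prob[q]
    p
  })

  draw_class <- function(n) {
    ans <- matrix(NA_integer_, nrow = n, ncol = nq)
    for (q in seq_len(nq)) {
      ans[, q] <- sample.int(nopt, n, replace = TRUE, prob = profiles[[q]])
    }
    ans
  }
  ans1 <- draw_class(spec$n1)
  ans2 <- draw_class(spec$n2)

  plant_slice <- function(n, size, offset) {
    if (size == 0) return(integer(0))
    (((offset + seq_len(size) - 1L) %% n) + 1L)
  }
  resample_excluding <- function(q, exclude_opt, n) {
    p <- profiles[[q]]
    p[exclude_opt] <- 0
    if (sum(p) <= 0) p <- rep(1, length(p)) * (seq_along(p) != exclude_opt)
    sample.int(nopt, n, replace = TRUE, prob = p)
  }

  plants <- spec$plants
  truth_rows <- list()
  if (nrow(plants) > 0) {
    n_pl <- nrow(plants)
    for (i in seq_len(n_pl)) {
      qs <- plants$questions[[i]]
      opt <- plants$option[i]
      for (side in 1:2) {
        n <- if (side == 1) spec$n1 else spec$n2
        target <- if (side == 1) plants$support_c1[i] else plants$support_c2[i]
        offset <- floor((i - 1) * n / n_pl)
        if (identical(plants$mode[i], "deterministic")) {
          size <- as.integer(ceiling(target * n - 1e-9))
          slice <- plant_slice(n, size, offset)
        } else {
          slice <- which(runif(n) < target)
        }
        outside <- setdiff(seq_len(n), slice)
        for (q in qs) {
          if (side == 1) {
            ans1[slice, q] <- opt
            redo <- outside[ans1[outside, q] == opt]
            if (length(redo) > 0) {
              ans1[redo, q] <- resample_excluding(q, opt, length(redo))
            }
          } else {
            ans2[slice, q] <- opt
            redo <- outside[ans2[outside, q] == opt]
            if (length(redo) > 0) {
              ans2[redo, q] <- resample_excluding(q, opt, length(redo))
            }
          }
        }
        realized <- if (side == 1) {
          mean(apply(ans1[, qs, drop = FALSE] == opt, 1, all))
        } else {
          mean(apply(ans2[, qs, drop = FALSE] == opt, 1, all))
        }
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          name = plants$name[i],
          class = CLASS_LEVELS[side],
          items = list(item_code(qs, opt)),
          target_support = target,
          realized_support = realized
        )
      }
    }
  }

  to_labels <- function(ans) {
    out <- as.data.frame(matrix(opt_labels[ans], nrow = nrow(ans)))
    names(out) <- paste0("Q", seq_len(nq))
    out
  }
  survey <- dplyr::bind_rows(
    dplyr::bind_cols(
      tibble::tibble(
        participant_id = seq_len(spec$n1),
        adherence = "adherent"
      ),
      to_labels(ans1)
    ),
    dplyr::bind_cols(
      tibble::tibble(
        participant_id = spec$n1 + seq_len(spec$n2),
        adherence = "non_adherent"
      ),
      to_labels(ans2)
    )
  )

  structure(
    list(
      survey = tibble::as_tibble(survey),
      codebook = codebook,
      truth = list(
        plants = if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
          tibble::tibble(name = character(), class = character(),
                         items = list(), target_support = numeric(),
                         realized_support = numeric()),
        regression = spec$regression,
        seed = spec$seed
      ),
      spec = spec
    ),
    class = "crcs_simulation"
  )
}

#' Draw a binary outcome from a logistic regression scenario
#'
#' Given a numeric covariate table and a scenario with known coefficients,
#' draws `Bernoulli(plogis(intercept + X beta))` outcomes. Used for
#' coefficient-recovery and coverage experiments.
#'
#' @param covariates A data frame whose columns match
#'   `names(scenario$coefficients)`.
#' @param scenario A list with `coefficients` (named) and `intercept`, e.g.
#'   [default_regression_scenario()].
#' @return An integer 0/1 vector of length `nrow(covariates)`.
#' @export
generate_regression_outcome <- function(covariates, scenario) {
  cf <- scenario$coefficients
  missing_x <- setdiff(names(cf), names(covariates))
  if (length(missing_x) > 0) {
    abort(paste0("covariate column(s) missing: ",
                 paste(missing_x, collapse = ", ")))
  }
  X <- as.matrix(covariates[, names(cf), drop = FALSE])
  eta <- scenario$intercept + as.numeric(X %*% cf)
  rbinom(nrow(X), 1L, plogis(eta))
}

#' Simulate a complete regression dataset with known truth
#'
#' Binary predictors drawn with the scenario's `predictor_prob`, outcome
#' from [generate_regression_outcome()].
#'
#' @param n Number of records.
#' @param scenario Scenario list (default [default_regression_scenario()]).
#' @param seed Optional integer seed.
#' @return A tibble with `.outcome` and one column per predictor.
#' @export
simulate_regression_data <- function(n, scenario = default_regression_scenario(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- scenario$coefficients
  X <- tibble::as_tibble(
    setNames(
      lapply(names(cf), function(nm) {
        rbinom(n, 1L, scenario$predictor_prob %||% 0.5)
      }),
      names(cf)
    )
  )
  out <- tibble::tibble(.outcome = generate_regression_outcome(X, scenario))
  dplyr::bind_cols(out, X)
}
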