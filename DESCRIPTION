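Package: crcsmine
Title: Class-Conditional Association Mining for Cancer-Screening Adherence Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining categorical health-survey data for itemsets that
    discriminate between screening-adherent and non-adherent respondents.
    Survey responses are encoded as disjoint question-option items, frequent
    itemsets are extracted per adherence class with the Apriori algorithm and
    reduced to maximal supersets, and contrast rules (strong class itemsets,
    shared itemsets with large support differences, and class-unique
    extensions of shared subsets) select candidate variables that a
    confirmatory logistic regression then quantifies with odds ratios,
    pseudo-R-squared statistics, a Hosmer-Lemeshow test and a classification
    table. A synthetic survey generator with planted itemsets of known
    per-class support makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
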