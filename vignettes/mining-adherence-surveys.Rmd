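---
title: "Mining screening-adherence surveys: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining screening-adherence surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcsmine)
```

## The analysis model

`crcsmine` treats a categorical survey as a transaction database. Each
question-option pair is one item, coded `question_id * 1000 + option_index`
so that codes are globally unique, decode uniquely, and match the style of
identifiers used in survey mining reports (item `130001` is option 1 of
question 130). A respondent's record is the set of items for the questions
they answered — at most one item per question, nothing for blanks.
"Refused" and "Don't know" are ordinary options with their own codes: a
refusal is an observed response, and refusal patterns can themselves be
class-discriminating.

The binary outcome is guideline adherence to colorectal cancer screening:
a respondent is adherent when they report a fecal occult blood test within
1 year, a sigmoidoscopy within 5 years, or a colonoscopy within 10 years.
The colonoscopy guideline window is 7–10 years depending on individual
risk; we default to the 10-year outer bound and expose the interval as an
argument (`screening_history()`). A test never taken contributes `FALSE`,
and unknown history fields also resolve to `FALSE` — an unknown history
cannot demonstrate adherence — with the number of such imputations
recorded on the result. The rule is monotone: additional qualifying
screening can never remove adherence.

### Frequent itemsets and contrasts

Within each class, the support of an itemset is the fraction of records
containing it. Mining uses the classic Apriori level-wise search: size-k
candidates are joins of size-(k−1) frequent itemsets sharing a (k−2)
prefix, pruned when any (k−1)-subset is infrequent, with
question-disjointness enforced at join time (two options of one question
can never co-occur, so discarding those joins early changes nothing
semantically). Frequency is decided on counts, not floating-point
fractions: an itemset is frequent iff its count is at least
`ceiling(min_support * n)`, with a guard for values like 0.6 × 411 = 246.6
that are not integral. The threshold comparison is inclusive — exactly 60%
of records is frequent at 0.6.

Three extractions turn per-class frequent itemsets into contrasts:

* **Strong class itemsets** (`strong_itemsets()`): support at least `high`
  (default 0.8) in the target class and strictly below `low` (default 0.6)
  in the other, maximal-filtered within the selection, each reported with
  the confidence of the rule itemset → class. We read "does not appear
  with support above 60%" as strict `< 0.6`; an itemset at exactly 0.6 in
  the other class is excluded.
* **M1** (`m1_itemsets()`): itemsets frequent in *both* classes whose
  absolute support difference is at least 0.20 — percentage points, not a
  relative ratio. Inclusive at the boundary: a gap of exactly 20 points
  qualifies. An itemset frequent in only one class never enters M1,
  however large its gap.
* **M2** (`m2_itemsets()`): for each itemset frequent in exactly one
  class, every non-empty proper subset frequent in both classes yields a
  (shared subset, class-unique extension) pair. By default only maximal
  qualifying subsets are reported: if B qualifies, so does every non-empty
  subset of B, and reporting them all floods the output with entries that
  carry no extra information. `all_subsets = TRUE` restores the full list,
  and the oracle tests compare that full list against a direct
  set-comprehension. An empty M2 side is a legal outcome — with few
  class-unique itemsets in one class there may simply be nothing to
  report.

No confidence cutoff is applied anywhere: confidence is computed and
reported on every emitted rule, but the selection criteria are support
arithmetic only. Statistical significance is deliberately deferred to the
regression stage rather than handled with contrast-set corrections, which
keeps the mining stage a pure description of the data.

All outputs are deterministically ordered (by class, then descending
support or difference, ties broken lexicographically by item codes), so
identical inputs serialize identically.

### The confirmatory regression

`fit_adherence_model()` fits adherence on the mining-selected variables by
maximum likelihood (IRLS via `glm`, tolerance 1e-10, at most 100
iterations) after listwise deletion. Binary survey items enter as 0/1
indicators and Likert-type items as ordinal integers (`design_spec()` +
`encode_design()`); the coding map is explicit configuration because
coefficient signs depend on it — recoding an indicator in the opposite
direction flips B to −B and maps the odds ratio to its reciprocal — and we
always report `OR = exp(B)` with the 95% Wald interval
`exp(B ± 1.96 SE)` and Wald statistic `(B/SE)²`.

Pseudo-R² follows Cox & Snell, `1 − exp(2(LL0 − LL1)/n)`, with
Nagelkerke's rescaling by its attainable maximum. The Hosmer–Lemeshow test
sorts records by fitted probability into at most 10 groups, never
splitting ties: with a handful of binary predictors the distinct covariate
patterns cap the group count, so g can fall below 10 and df = g − 2 below
8 (seven patterns give df = 5). Fewer than three groups makes the test
undefined and is an error rather than a silent df of 0. Separation is
detected as a diverging coefficient (|B| > 15 after convergence) and
reported as an error naming the predictor; rank-deficient designs are
refused with the collinear columns listed.

## The synthetic generator

Real telephone-survey microdata of this kind are generally not
depositable, so `simulate_survey()` generates surveys with the structure
the pipeline assumes: two classes of 608 and 411 respondents (1019
records), 144 questions with 5 options each (720 items), and answers
independent given class. Class profiles are identical apart from planted
patterns, which makes the no-plant configuration an honest null: any
strong or M1 discovery there is a false positive, and the tests check the
null configuration is empty in at least 18 of 20 seeds.

A quarter of questions are "consensus" questions whose dominant option has
probability drawn once per question from U(0.70, 0.88); the rest are
"diverse" (dominant probability U(0.25, 0.50)). Consensus questions are
what give the null data a realistic frequent-itemset landscape —
co-occurring high-frequency answers produce multi-item frequent itemsets
at the 0.6 threshold, of the kind a real survey shows for near-universal
responses ("has a usual place of care"). The 0.88 ceiling is deliberate:
a background item with marginal probability p co-occurs with a planted
itemset of support s at roughly s·p, and keeping p ≤ 0.88 keeps every
such union below the 0.8 strong threshold (0.85 × 0.88 ≈ 0.75, four
standard deviations clear of 0.8 at these sample sizes), so background
noise cannot displace a planted strong itemset under maximal filtering.

Deterministic plants overwrite the planted questions' answers in a
contiguous slice of exactly `ceiling(s·n)` records and remove the planted
option outside the slice, so realized support is exact by construction.
Slices for different plants start at evenly staggered cyclic offsets
rather than all at record 1: nested prefix slices would make every pair of
plants co-occur as an artificial union super-itemset with support equal to
the smaller plant's, which in turn would displace the individual plants
from maximal-filtered output. With staggered offsets the default plant
unions sit at pairwise overlaps of 0.52–0.75, below the strong threshold,
while each plant's own support stays exact. The default plant set
exercises each rule family at its boundary: a strong pair at 0.85/0.55, an
M1 pair at 0.85/0.62 (a 23-point gap), and an M2 configuration (shared
singleton at 0.90/0.90 whose extension is frequent only in the adherent
class). Stochastic plants (Bernoulli inclusion) are available for
robustness experiments where sampling error in the realized support is
wanted.

All randomness flows through the single integer seed in
`generator_spec()`; the same seed yields byte-identical tables.

What the generator does **not** emulate: correlation between questions
within a class (answers are class-conditionally independent), realistic
demographic marginals, attitude-scale structure, or item non-response
patterns. Passing the planted-recovery tests therefore shows the pipeline
correctly extracts patterns of stated strength from data matching its
independence assumptions — not that any particular real survey contains
such patterns, nor that the method is robust to strong inter-question
dependence. An optional dependence hook was considered and left out: the
contrast definitions are purely support arithmetic, so their correctness
does not depend on the independence structure, only the false-positive
monitoring does.

## Numerical choices and degenerate inputs

* Support thresholds compare counts against `ceiling(threshold * n)` with
  a 1e-9 guard; support *values* are exact rationals count/n.
* Strict inequalities (strong `low` bound) and inclusive ones (mining
  threshold, M1 gap) carry 1e-12 guards so that exact boundary fractions
  land on the intended side.
* Empty classes make support undefined and raise errors; the empty
  itemset (support 1 by convention) is excluded from tables; singletons
  are ordinary itemsets until maximal filtering.
* The exhaustive enumerator `brute_force_itemsets()` is guarded at 16
  distinct items; it exists as an in-package oracle and for tiny studies,
  not as an alternative mining path.
* `apriori_itemsets()` is guarded at one million frequent itemsets. At
  full survey scale the frequent collection grows explosively as the
  threshold drops (this exploration regime is what distributed mining
  frameworks exist for), and a 10%-grid sweep below roughly 0.4 is not
  tractable in memory on a single machine; the guard converts that into a
  diagnostic error recommending a higher threshold. The `support_sweep()`
  grid is fully configurable, so exploratory sweeps can be run on
  down-sampled data or over a truncated grid.
* The regression refuses single-level outcomes after listwise deletion,
  collinear designs, and separated fits, each with a named diagnostic.

## Problem sizes used in the test-suite experiments

Oracle-equivalence tests run 200 random datasets of up to ~12 items and
100 records, a size where exhaustive enumeration is exact and fast.
Planted-recovery and null-configuration checks run the full 1019 × 144
study scale across 20 seeds. Coverage of the 95% Wald intervals uses 200
replicates at n = 1000 with true coefficients (−1.5, 1.5, −0.3), sized so
the binomial width of the coverage estimate (±1.5 points) sits inside the
93–97% acceptance band; bias-shrinkage checks use n ∈ {500, 2000, 8000}
with 50 replicates each.
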