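---
title: "Log-linear agreement models for CAD reader studies without a gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-linear agreement models for CAD reader studies without a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agreelog)
```

## The problem

When a computer-aided diagnosis (CAD) system is evaluated against human
readers and no gold standard exists, the natural data object is the K-way
contingency table cross-classifying every subject by the category each
rater assigned.  ROC analysis needs a binary truth; a kappa coefficient
compresses the whole table into one number.  Neither can answer the
question that actually matters for deployment: *is the CAD system
statistically interchangeable with an expert reader?*

agreelog answers it with log-linear models for the cell counts.  Writing
$\mu_{c_1 \dots c_K}$ for the expected count of the cell in which rater
$k$ read category $c_k$,

$$
\log \mu = u
  + \sum_{k=1}^{K} u_k(c_k)
  + \sum_{S, m} \delta_{S,m}\, I_{S,m},
$$

where $u$ is the overall effect, $u_k(\cdot)$ the main effect of rater
$k$ (the *chance* component: with nothing else this is the independence
model), and $I_{S,m}$ indicates that every rater in the subset $S$
assigned category $m$.  The $\delta_{S,m}$ measure *beyond-chance*
agreement: how much more often the raters in $S$ land together on $m$
than their margins predict.

## The model ladder

`agreement_spec()` names the nested sequence the package fits:

* **independence** — chance only;
* **homogeneous** — one shared diagonal-agreement strength (all raters,
  any category);
* **nonhomogeneous** — one strength per category;
* **pairwise_homogeneous / pairwise_nonhomogeneous** — one term per
  unordered rater pair (K ≥ 3), shared or per category;
* **threeway_homogeneous / threeway_nonhomogeneous** — one term per rater
  triple, *replacing* the pairwise terms.

The replacement in the three-way models (rather than adding triples on
top of pairs) is a deliberate design choice: on a 4-rater, 3-category
table it yields residual degrees of freedom 81 − 9 − 4 = 68 and
81 − 9 − 12 = 60, the df accounting under which the three-way analysis
of this family of models is conventionally reported, and it keeps the
homogeneous → nonhomogeneous pair of each mode a clean 1-vs-C-parameter
nesting.  `nested()` verifies nesting by actual column-space containment
of the two designs, not by name.

`model_ladder()` fits the rungs in order and selects the **first** rung
whose deviance goodness-of-fit p-value (G² against chi-square on the
residual df) is at or above `selection_alpha = 0.05`.  Selecting the
first adequate rung — not the global best — is the tie-break: the aim is
the most parsimonious description of the agreement structure.  Once a
model is selected, individual coefficients and the equivalence
hypotheses are tested at the more conservative `test_alpha = 0.01`,
acknowledging the multiplicity of post-selection tests.  Model-vs-model
comparisons use the likelihood-ratio test (`lr_test()`); hypotheses on
coefficients of one fitted model use the Wald chi-square
(`wald_test()`), with an equality of three strengths encoded as two
independent difference rows.

## Equivalence of the CAD reader

With three experts and one CAD reader, `equivalence_tests()` partitions
the pair (or triple) strengths of the category-specific fit by CAD
membership and tests, per category $m$:

* the within-expert pair strengths are equal;
* the CAD–expert pair strengths are equal;
* $\sum \delta_m^{\text{expert pairs}} = \sum \theta_m^{\text{CAD pairs}}$
  (pairwise mode), or
  $\delta_m = \tfrac13\sum\theta_m$ (three-way mode).

Failing to reject the last hypothesis at $\alpha = 0.01$ is the
operational meaning of "the CAD system is equivalent to an expert":
the agreement pattern does not change when the CAD reader replaces an
expert in a pair or triple.

## Parameterization and coding

Two coding conventions coexist, on purpose.

* **Main effects** use reference coding against the *last* declared
  category by default (`main_coding = "reference"`), with sum-to-zero
  coding available.  Agreement estimates, their SEs, fitted counts and
  every G² are invariant to this choice; a property test enforces the
  invariance to 1e-6.
* **Agreement indicators** are effect-coded ±1 by default
  (`agree_coding = "effect"`).  This is the parameterization used by the
  classical categorical-modelling procedures in which this model family
  has historically been fitted and reported, so the printed coefficients
  of published analyses are reproduced on their own scale.  Plain 0/1
  dummies are available (`agree_coding = "dummy"`); dummy estimates are
  exactly twice the effect-coded ones, and all tests and fit statistics
  are identical under either.

The **generator** functions default to dummy coding instead.  A dummy
strength reads directly as the log-odds boost of an all-agree cell, and
moderate strengths produce realistic tables; the same numbers pushed
through ±1 columns accumulate large negative offsets on every
non-agreeing cell and concentrate essentially all probability mass in
one cell — nothing like a reader study.  `recovery_study()` refits with
the generating coding so truth and estimates share a scale.

## The synthetic-data generator

`cell_probabilities()` exponentiates the design at user coefficients and
normalizes; `sample_table()` draws one multinomial sample of fixed size
n — the design of a reader study with a fixed subject panel, not
independent Poisson cells (Poisson ML is valid for the agreement
parameters under either sampling scheme).  Seeds are explicit arguments;
the caller's RNG stream is saved and restored, and a fixed seed
reproduces tables bit-exactly.

The preset `paperlike4()` mimics the renography study the package's
fixture comes from: 4 raters (three experts, one CAD system), 3 ordered
categories, n = 185 kidneys, pairwise category-specific strengths set to
the published two-reader-at-a-time estimates, and shared per-rater main
effects (0.28, 0.39 against the obstructed baseline) solved once so that
each rater's marginal distribution approximates the study's 65/16/19%
split *after* the agreement terms act — the agreement terms themselves
pull mass onto the diagonal, so naive margins-as-main-effects would not
reproduce the study's prevalence.

What the generator deliberately does **not** emulate: the within-patient
correlation of the two kidneys of one patient (the study treats 185
kidneys from 95 patients as independent units, and the package
replicates that choice without a correction), reader drift or
rater-specific bias processes, and missing or incomplete readings
(`build_table()` drops incompletely rated subjects with a logged count).
Passing Monte-Carlo checks therefore show correctness of the estimator
and tests *under the stated sampling model*, not robustness to clustered
or missing real-world data.

## Numerical choices

* **Fitting**: Newton scoring on the Poisson log-likelihood with
  step-halving, started from the closed-form independence fit (log
  product-of-margins expected counts, floored at 1e-8).  Convergence
  requires relative log-likelihood change below 1e-10 together with
  either max absolute score below 1e-8 or every Newton-step coordinate
  below 1e-10; the step test is the scale-free escape for large tables,
  where the score's floating-point noise floor (which grows with n) can
  sit above the absolute tolerance even at the optimum.  Iteration cap
  100.
* **Covariance**: inverse Fisher information at the optimum; coefficient
  p-values are two-sided normal, contrast tests chi-square upper tail.
* **Sampling zeros** stay in the table with their structural role.  An
  agreement indicator whose active cells are all empty has no finite ML
  estimate; the fit aborts naming the divergent parameter rather than
  returning a silently huge number.
* **Sparse tables**: goodness-of-fit p-values use the chi-square
  approximation regardless of sparsity, matching how these models are
  used in practice, but a warning is issued when more than 20% of fitted
  counts fall below 5 (which already happens on the 185-kidney flagship
  table).
* **Two categories**: the category-specific two-rater model is
  saturated — its second diagonal indicator is a linear combination of
  intercept, main effects and the first indicator — so its design is
  refused as rank deficient, with the dependent column named.

## Problem sizes of the simulation checks

The packaged Monte-Carlo checks use n = 20,000 subjects per replicate
with 200 replicates for parameter recovery (|bias| < 0.05, 95%
Wald-interval coverage within [0.92, 0.98] per agreement parameter) and
500 replicates for the type-I error of each named equivalence test
(rejection rate within two binomial standard errors of the nominal
0.01).  These sizes put the Monte-Carlo error of a coverage or rejection
estimate near half a percentage point, sharp enough to detect a
miscalibrated test while keeping the whole suite in the tens of
seconds.

## Known limitations

* Categories are treated as nominal with diagonal-agreement terms; no
  ordinal association structure (linear-by-linear, quasi-symmetry) is
  modelled.
* Kappa is provided as a descriptive comparator only, without an SE or
  CI.  A published weighted kappa for the same data can legitimately
  differ from the linear-weighted value computed here (≈0.71 vs a
  published 0.72 for the flagship table) because weighting schemes and
  data handling vary between analyses; the package makes no attempt to
  reverse-engineer another study's kappa.
* Inference is asymptotic throughout: no exact conditional tests, no
  bootstrap CIs, no sparsity corrections beyond the warning.
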