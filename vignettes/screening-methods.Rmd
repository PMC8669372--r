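---
title: "Fuzzy multi-criteria screening: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy multi-criteria screening: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcoscreen)
```

## The screening model

`pcoscreen` turns a 31-item symptom questionnaire into one of four
diagnostic categories. The premise is that the raw data are linguistic —
subjects answer "fairly irregular" or "most of the time", not numbers — and
that the mapping from symptoms to diagnosis is itself vague. Both kinds of
vagueness are represented by triangular fuzzy numbers (TFNs): triples
$(l, m, u)$, $l \le m \le u$, with membership 1 at the mode $m$ and 0
outside $[l, u]$. Arithmetic is component-wise (`+`, `*`), the reciprocal is
$(1/u, 1/m, 1/l)$, and a TFN collapses to a crisp value by centre of area,
$(l + m + u)/3$.

Three stages compose the pipeline.

**Criterion weighting (fuzzy AHP).** Experts compare criteria in pairs on a
nine-intensity linguistic scale (Equal … Extreme important, each a TFN;
the inverse judgment is the TFN reciprocal). From the resulting reciprocal
matrix, row-wise fuzzy geometric means $r_i$ give fuzzy weights
$\tilde w_i = r_i \otimes (r_1 \oplus \dots \oplus r_n)^{-1}$, which are
defuzzified by centre of area and normalized to sum to one. The
denominator of the normalization is the sum of the defuzzified weights —
the only reading under which the weights are a probability-like vector,
and the one consistent with the shipped default weight fixture (whose
printed three-decimal values sum to 0.997). The expert judgment matrix
behind that fixture is not published, so the package ships the normalized
weights themselves (`default_criterion_weights()`); any judgment set can be
supplied via `fuzzy_ahp()`. A Saaty consistency ratio on the defuzzified
matrix is available behind `check_consistency` (default off): it is a
diagnostic the weighting procedure itself never used, and its random-index
table only extends to 15 criteria.

**Channel ranking (fuzzy TOPSIS).** Each subject is screened on two
independent channels: physical (C11–C111) ranking P1 high / P2 normal / P3
moderate PCOS, and mental (C21–C45) ranking M1/M2/M3. Ratings on the
five-point VL–VH scale form the decision matrix; with $K$ raters a cell
aggregates as (min of lowers, mean of modes, max of uppers). At screening
time $K = 1$: the experts designed the scales and maps once, and the
per-subject run is automated. Every criterion is treated as a benefit
criterion and normalized by the column's largest upper support, then
weighted by the (degenerate-TFN-promoted) crisp AHP weights. Per
alternative, vertex distances to the fuzzy positive and negative ideal
solutions are summed over criteria, and the closeness coefficient
$CC = d^-/(d^* + d^-)$ ranks the alternatives; the top level is the
channel's decision.

**Fusion (rule base).** Nine rules — data, not code — map the level pair to
a category: A1 both conditions, A2 only PCOS, A3 only mental-health issues,
A4 normal. The validated default sends every high/moderate pairing on both
channels to A1; it is deliberately asymmetric ((P3, M3) fuses to A1 while
(P2, M3) fuses to A3), and the package reproduces that asymmetry as stated
rather than rationalizing it. Level selection is by maximum closeness
coefficient only; no CC-magnitude threshold is applied.

On labelled cohorts, `screen_cohort()` adds the confusion matrix, accuracy,
and the wellness indicators
$I_M = 100\,n\{(P1 \lor P3) \land A1\}/n\{P1 \lor P3\}$ and the symmetric
$I_P$ over M1/M3, both erroring on an empty denominator.

## Numerical and representational choices

- **Distance metric.** The separation step needs a distance between TFNs
  that the original TOPSIS formulation leaves unnamed. The package uses the
  vertex method, $d_v(a,b) = \sqrt{\frac{1}{3}\sum_{k}(a_k - b_k)^2}$, the
  standard companion of this formulation; the shipped reference distances
  are consistent with it at the closeness-coefficient stage, which is the
  only stage they anchor (the raw ratings behind them are unpublished).
- **Ideal solutions are scalars.** FPIS/FNIS are per-criterion crisp values
  (max upper / min lower); they are promoted to degenerate TFNs $(c, c, c)$
  before $d_v$, which keeps the metric well-typed.
- **Ties** in ranking break by declared alternative order (P1, P2, P3);
  ties never arise in non-degenerate data but the rule makes the ranking a
  total function.
- **Negative supports** are rejected in products and reciprocals; every
  scale in the instrument is non-negative, so a negative support signals a
  configuration error, not a modelling need.
- **Per-class counts.** With rows = actual, the reference evaluation
  computed FP from row sums and FN from column sums — the reverse of the
  textbook orientation. `per_class_counts(convention = "study")` reproduces
  that literally (default), `"standard"` gives the conventional one. The
  reference TN formula would double-count the diagonal; the package uses
  inclusion–exclusion, $TN_c = N - r_c - c_c + TP_c$, under both
  conventions, so that $TP + FP + FN + TN = N$ per class.

## The answer-to-rating bridge

The instrument's answer vocabularies and the expert map from answers to
alternative ratings are not published. The package therefore ships both as
replaceable configuration with documented defaults:

- **Instrument** (`inst/extdata/instrument.yaml`): five ordered levels per
  item, least symptomatic first — K10 items use the canonical K10 frequency
  scale, physical items use item-appropriate vocabularies.
- **Rating map** (`default_rating_map()`): monotone — at the most
  symptomatic level the "high" alternative rates VH and "normal" VL,
  reversed at the other end, with "moderate" peaked mid-scale
  (L, H, VH, H, L). This reproduces the qualitative behaviour of the
  reference worked example: a severe answer sheet selects the high level
  with moderate ranked above normal.

Because these defaults are declared rather than inferred, absolute closeness
coefficients on real cohorts are not comparable to the reference ones;
ordering behaviour and every downstream computation are.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 624 subjects by default,
category priors (0.22, 0.14, 0.26, 0.38) matching the observed A1–A4
test-set mix, and class-conditional categorical answers — A1 symptomatic on
both channels, A2 only physical, A3 only mental, A4 neither. `separation`
interpolates each per-criterion distribution between uniform (0) and a
one-hot mass on the most/least symptomatic level (1); the default 0.9 gives
strong but noisy structure, which we consider realistic for a
screening-positive spectrum. Answers are conditionally independent given
the class.

What passing tests on these cohorts show: the pipeline's plumbing,
monotonicity (accuracy non-decreasing in separation), and exact recovery in
the degenerate one-hot limit. What they do not show: performance on real
cohorts, where answers correlate within and across channels, class-
conditional distributions are not monotone in a single severity axis, and
expert labels carry their own noise. The headline accuracies shipped as
regression fixtures come from the reference evaluation, not from synthetic
data.

One consequence of the indicator definitions worth noting: at separation 1
the pipeline recovers every label, so $I_M$ equals the A1 share among
A1 + A2 subjects — it reaches 100% only in cohorts with no PCOS-only
class. The tests assert exactly that identity rather than a blanket 100%.

## Machine-learning baselines

The comparison protocol ordinal-encodes answers (0-based, declared level
order), splits 80/20 stratified by class, balances the *training partition
only* by nearest-neighbour means — each synthetic row is the mean of a
random minority sample and its $k = 5$ within-class Euclidean neighbours,
anchor included, $k$ clamped for small classes — and fits SVM (radial
kernel), KNN ($k = 5$) or a CART tree (unconstrained). The upstream
description leaves the oversampler's mean ambiguous (with or without the
anchor); including the anchor degrades gracefully at $k = 1$. Stratification
is likewise an inference: the reference per-class test counts imply all four
classes present in the test set. Splitting precedes balancing even though
the reference test-set size (167 of 624) suggests the original order may
have differed; that bookkeeping discrepancy is documented, not imitated.
Hyperparameters were not specified upstream; the defaults above are
exposed through `params`.

## Problem sizes

The test suite runs cohorts of up to 600 subjects (three seeds, three
separation settings) for the monotonicity property and 80–250 subjects
elsewhere; property checks sample 20–100 random TFN triples and 2–4
criterion matrices per size. The whole suite completes in well under a
minute on one core.

## Known limitations

- The 31×31 expert judgment matrix, the answer vocabularies and the expert
  rating map are unpublished; the shipped defaults are declared stand-ins,
  so end-to-end reproduction of the reference worked example is anchored
  only from the distance tables forward.
- The K10 items are treated as ten separate criteria; the instrument's
  published clinical cut-offs on the summed score are out of scope.
- All criteria are benefit criteria; cost-form normalization, trapezoidal
  or type-2 fuzzy sets, and other MCDM methods (VIKOR, PROMETHEE) are out
  of scope.
- The final category is crisp; no graded category membership is emitted.
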