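---
title: "Screening edible-oil manufacturers from B2B e-invoices"
author: "oilalarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening edible-oil manufacturers from B2B e-invoices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oilalarm)
```

## The problem

Edible-oil fraud — cutting food oil with recycled or industrial
material — is hard to catch chemically: adulterated product can be
tuned to pass compositional standards. What convicted manufacturers in
the incidents that motivated this design was not chemistry but
*irrational bookkeeping*: they sold far more oil product than the raw
material they verifiably purchased, because much of their input was
never invoiced as a proper ingredient. Where business-to-business
electronic invoicing is compulsory, that asymmetry is visible in the
transaction stream itself, and a regulator can screen every
manufacturer continuously instead of inspecting a few.

Two obstacles stand between the raw invoice stream and that screen,
and they define the package's two stages:

1. manufacturers transact in many goods, so oil-related lines must be
   *sieved* from item-name text;
2. monthly purchase/sales totals are noisy, so the anomaly statistic
   must be robust to month-boundary artifacts.

## Stage 1: the text sieve

Item names are short, noisy strings ("Refined Soybean Oil 18L"). The
sieve works on a labeled item table (name, binary edible-oil label):

* `keyword_filter()` first restricts attention to names containing a
  keyword (default `"oil"`) — cheap, but it keeps confounders such as
  motor oil or massage oil (in the original Chinese-language corpus,
  even soy sauce and cosmetics share the oil character);
* `normalize_and_tokenize()` case-folds, strips punctuation and drops
  digit-bearing tokens;
* `build_topics()` weights token counts by TF–IDF and projects them on
  the leading `m` right-singular vectors of the weighted
  document–term matrix (truncated SVD). This latent-semantic
  construction stands in for proprietary text-topic tooling whose
  internals are unpublished; it is the closest widely understood
  analogue. Singular-vector signs are fixed by making each vector's
  largest-magnitude entry positive, so refits are bit-identical.
  `keyword_featurizer()` is the expert alternative: binary indicators
  for a hand-chosen keyword list, optionally reduced by
  `select_features()` (chi-square ranking, ties broken by index);
* `train_sieve()` fits one of five backends (`knn`, `linear-svm`,
  `logistic`, `feedforward-net`, `random-forest`) with a stratified
  80/20 split; hyperparameters come from small fixed grids (k ∈ {3, 5,
  7}; SVM cost ∈ {0.1, 1, 10}; net size ∈ {3, 5} at decay 0.1; 200
  trees) chosen by stratified 5-fold cross-validation *inside* the 80%
  training portion, with the reported sensitivity/specificity/error
  measured on the untouched 20%. Where a published protocol mentions
  both a held-out split and cross-validation without spelling out
  their interaction, this nesting is the reading we adopt: CV selects,
  the holdout measures.

The tokenizer is deliberately simple and English-oriented: the
synthetic fixtures use English templates, and the tokenizer is the
single place to swap in a character-n-gram scheme for ideographic
scripts.

## Stage 2: turnover features and the alarm

Sieved invoices are summed per manufacturer and calendar month into
purchases `Pur_i` (manufacturer as vendee — its downstream side) and
sales `Sale_i` (as vendor — upstream). Months without transactions are
zero-filled: the *absence* of purchase invoices is precisely the
signal of interest. Because goods bought on the first of a month are
no different from goods bought on the last day of the previous one,
the series are smoothed with a trailing 3-month moving average,

$$D_i = \tfrac{1}{3}(Pur_{i-2} + Pur_{i-1} + Pur_i), \qquad
  U_i = \tfrac{1}{3}(Sale_{i-2} + Sale_{i-1} + Sale_i),$$

a fuzzification of the artificial month boundary that also damps
noise. The features are

$$X_1 = \log(U_i / D_i), \qquad X_2 = \log(U_i / D_{i-1}),$$

natural logarithms; $X_2$ captures the lag between buying material and
selling product. The naive decision rule flags a month record as
suspicious iff $X_1 > 6$ **and** $X_2 > 6$, strictly: sales more than
$e^6 \approx 403$ times recorded purchases across a two-month span.
The same five backends can be trained on (X1, X2) using benchmark (A)
and problematic (B) month records, and `fit_ellipse()` describes the
benchmark cloud with 95%/99% bivariate-normal prediction regions
(squared Mahalanobis radius equal to the $\chi^2_2$ quantile). The
ellipses are descriptive and an optional outlier screen; they do not
feed the classifiers. `screen_unlabeled()` applies a rule or trained
model to unlabeled manufacturers and flags those with at least `k`
suspicious months (default `k = 1`; the aggregation from month flags
to manufacturer flags is our choice — sources that report manufacturer
counts do not state one).

### Numerical choices

* **Warm-up.** Features are emitted only for full 3-month windows: a
  series of M months yields M−2 values of $X_1$ and M−3 of $X_2$
  (the first smoothed month has no full-window $D_{i-1}$). Partial
  windows would silently change the estimator; published record
  counts already reflect unitemized missingness, so nothing anchors an
  alternative.
* **Zero denominators.** A window with zero purchases but positive
  sales is conceptually $X = +\infty$ — maximally suspicious. Rather
  than propagate non-finite values, the log-ratio is clamped to a
  configurable cap (default 20, far above the threshold 6) and the
  record flagged `clamped`; symmetric at $-20$ for zero sales. Both
  sides zero carry no information: `valid = FALSE`, features `NA`.
  Clamped records participate in the naive rule but are excluded from
  classifier training by default — they are distributional outliers by
  construction.
* **Boundary.** The rule is strictly exclusive: a record at exactly
  (6, 6) is benchmark. A record lacking $X_2$ classifies as benchmark
  by convention and is marked partial.
* **Rounding.** Percentages render half-up to two decimals
  (`round_half_up()`), matching the published tables' formatting;
  `implied_error_rate()` rounds implied error *counts* to the nearest
  integer — the only reading under which five of the six rows of the
  published stage-2 performance table are self-consistent. The
  remaining row (the naive tree's printed 3.97%) is inconsistent with
  its own printed sensitivity/specificity and the 27/425 class sizes,
  which imply 10/452 = 2.21%; the package computes error rates from
  confusion counts and documents the discrepancy instead of matching
  it.

## The synthetic generator

Real national e-invoice corpora are access-restricted, so every stage
is exercised against `generate_invoices()`, which emulates the
reported structure of such data at desk scale. Defaults are the study
conditions: 21 benchmark (A) and 6 problematic (B) manufacturers, 46
months from January 2014, `sigma_log = 0.5`, `b_shift = 8`,
`p_suspicious = 0.5`, with a 60/40/40 item catalog (≈26% of items
edible-oil-related, matching the class balance of the real labeled
item table).

* **Item names** come from three template strata sharing only the
  token "oil" (edible oils; oil-bearing confounders like motor oil;
  unrelated goods). Digit-bearing pack sizes extend the unique-name
  space without entering the token vocabulary. With disjoint stratum
  vocabularies the sieve is separable *by construction* — passing
  sieve tests show the machinery recovers recoverable structure, not
  that any classifier would reach these numbers on real, messier text.
* **Monthly totals.** Benchmark months draw
  $\log(Sale/Pur) \sim N(0, \sigma_{\log})$ around a
  manufacturer-level scale; totals are split into a Poisson number of
  invoice lines with exponential weights, plus distractor invoices
  over non-edible items on both sides, so the sieve is load-bearing
  rather than decorative.
* **Suspicious months** suppress the *purchase* total by
  $e^{-b\_shift}$ — unreported input purchases — rather than inflating
  sales, keeping sales magnitudes comparable across classes. The
  default shift of 8 puts suspicious windows at $X \approx 8$, clearly
  above the threshold 6 but finite.
* **Episodes.** A problematic manufacturer's suspicious months form
  one contiguous episode at the end of its series, with binomially
  drawn length (expected fraction `p_suspicious`): a fraud regime that
  persists until records cease, as in the incidents that motivated the
  design. This matters for evaluation: under 3-month smoothing an
  *isolated* suspicious month is undetectable in principle (its
  window average is dominated by neighbouring normal purchases), so
  month-level label recovery is only well-posed for records whose
  whole window sits in one regime. Accordingly
  `suspicious_record_labels()` labels a feature record problematic iff
  all raw months in its 4-month span (the union of the $D_i$ and
  $D_{i-1}$ windows) are suspicious; mixed-window boundary records are
  labelled benchmark, and their intermediate features classify
  benchmark too.
* **Determinism.** One master seed; per-manufacturer sub-streams by a
  stable string hash of the manufacturer id, so corpora are
  reproducible record for record across runs and platforms.
* **C manufacturers** mix the two regimes: each behaves like B with
  probability `c_suspicious_prob` (default 0.05), else like A.

What the generator does **not** emulate: real (Chinese) item-name
text and naming idiosyncrasy, tax and currency semantics, credit
notes and voided invoices, seasonal demand, cross-manufacturer
amount correlation, and any calibrated amount distribution — no
distributional description of the restricted corpus's amounts is
public, so the scales are realistic stand-ins, not estimates.

## Problem sizes and runtime

Tests and the acceptance script run at the study scale: ≈19,000
invoices per corpus, 1,188 month records, a 1,000-item catalog for the
sieve benchmark, 10,000 Monte-Carlo draws for ellipse coverage. These
sizes give comfortable Monte-Carlo margins (binomial standard error
≈0.002 at coverage 0.95 with n = 10,000) while keeping a full run in
tens of seconds.

## Limitations

* The topic construction is an analogue, not a reimplementation, of
  the proprietary tooling used on the original corpus; published
  per-cell sieve performance is not reproducible from outside and is
  not a target here.
* Month-level sensitivity is defined against regime-pure windows (see
  above); a detector for isolated anomalous months would need a
  shorter smoothing window and a different noise trade-off.
* The screen is an inspection-prioritization tool. Flags identify
  manufacturers whose bookkeeping warrants attention; they are not
  evidence of adulteration.
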