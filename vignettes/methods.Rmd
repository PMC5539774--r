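---
title: "Methods: discretization, attribute selection and Bayesian-network risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discretization, attribute selection and Bayesian-network risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskbn)
```

## The problem and the model

`riskbn` targets early-warning risk prediction from rectangular clinical
records: one binary outcome (canonically, whether a COPD patient goes on to
exacerbate) and tens of mixed continuous/discrete predictors, often with
weak individual signal and unknown mutual dependencies. The model class is a
Bayesian-network classifier over discretized attributes, whose joint
distribution factorizes as

$$P(V_1, \dots, V_n) = \prod_{i=1}^n P(V_i \mid Pa(V_i)),$$

with the class node parentless. Two structure learners are provided:

* **TAN** (tree-augmented naive Bayes): every predictor gets the class plus
  at most one predictor parent; the predictor tree is the maximum-weight
  spanning tree under conditional mutual information
  $I(X;Y \mid C) = \sum \hat P(x,y,c)\log_2
  \frac{\hat P(x,y\mid c)}{\hat P(x\mid c)\hat P(y\mid c)}$ (maximum-
  likelihood frequencies, $0\log 0 = 0$). This relaxes naive Bayes'
  independence assumption at the cost of one extra parent per node.
* **K2**: under a fixed node ordering, each node greedily acquires the
  predecessor parent that most improves the Cooper–Herskovits marginal
  likelihood $\sum_j [\ln\Gamma(r) - \ln\Gamma(N_j + r) +
  \sum_k \ln\Gamma(N_{jk}+1)]$, stopping at a parent cap that counts the
  class; a cap of 1 is exactly naive Bayes.

Parameters are multinomial CPTs with additive smoothing
$\hat P(v \mid pa) = (N_{v,pa} + s)/(N_{pa} + s\,r)$ over the *full*
Cartesian product of parent states; unobserved configurations become uniform
when $s > 0$. Inference is exact. Under full evidence the posterior is a
product of CPT lookups; under partial evidence unobserved predictors are
marginalized — by vectorized upward message passing on the predictor forest
for NB/TAN-shaped models, and by per-record variable elimination (greedy
min-width ordering) for general bounded-parent structures. Partial-evidence
inference is not a convenience: it is the mechanism behind the
incremental-observation evaluation below.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `smoothing` (pseudocount $s$) | 0.5 | additive CPT smoothing; keeps every posterior strictly inside (0, 1). 0 gives maximum-likelihood CPTs, with named errors when an unobserved configuration is used. |
| `cv_folds` | 10 | stratified cross-validation folds; per-fold class counts are within one of perfect stratification. |
| `max_parents` (K2) | 2 | total parent cap counting the class; 1 = naive Bayes. |
| `stale_limit` (best-first) | 5 | consecutive non-improving expansions before the search stops. |
| `population`, `generations` (genetic) | 20, 20 | genetic-search budget; crossover 0.6 and per-bit mutation $1/p$ are conventional defaults, stated rather than fitted. |
| `start_m` (incremental) | 8 | first evidence budget of the incremental evaluation — the number of attributes a front-line interface shows first. |
| cutoff rule | min-distance | ROC point minimizing $(1-\text{sens})^2 + (1-\text{spec})^2$, i.e. nearest the perfect corner; ties break toward the more sensitive threshold. |

All entropies and information measures are base-2 (bits), the convention of
the MDL and information-gain literature this builds on.

## Supervised discretization

Continuous predictors are cut by the Fayyad–Irani MDL criterion
(`mdl_discretize_attribute()`): candidate cuts are midpoints between
consecutive distinct values whose label sets differ (a mixed block makes
both flanking midpoints candidates — the boundary-point rule); the
top-down recursion takes the gain-maximizing candidate (ties toward the
smallest threshold, for determinism) and keeps it iff

$$Gain > \frac{\log_2(N-1)}{N} + \frac{\log_2(3^c-2) -
  [c\,Ent(S) - c_1 Ent(S_1) - c_2 Ent(S_2)]}{N}.$$

Intervals are half-open $[a, b)$: a value equal to a cut belongs to the
upper bin, one fixed convention asserted in tests. Attributes receiving no
cut become single-state, are flagged *inert*, and are excluded from
selection and structure learning — they carry no information and would put a
zero in every SplitInfo denominator. Values outside the training range fall
into the unbounded terminal intervals (logged, never fatal). The greedy
recursion is checked against an independent exhaustive-recursion oracle for
all random columns with $n \le 30$.

## Attribute selection

Two filters and two wrappers, sharing one forward best-first engine:

* **Gain-ratio ranking**: $GainRatio(T,A) = Gain(T,A)/SplitInfo(T,A)$,
  ranked descending; attributes with ratio strictly below
  $\alpha = \max(GainRatio)/2$ are eliminated (equality is kept). The
  "maximum" in the threshold rule is read as the maximum gain-ratio *value*,
  not a rank index — the comparison against individual gain ratios is
  dimensionally meaningless otherwise.
* **CFS**: subsets scored by Hall's merit
  $k\,\bar r_{zi}/\sqrt{k + k(k-1)\bar r_{ii}}$ with symmetrical uncertainty
  $2[H(X)+H(Y)-H(X,Y)]/[H(X)+H(Y)]$ as the correlation on discretized data
  (the standard choice for discrete attributes), searched by best-first with
  stale limit 5.
* **Wrapper best-first / genetic**: candidate subsets scored by the pooled
  out-of-fold AUC of the Bayesian classifier under a shared stratified fold
  plan (same folds for every subset: scores stay comparable and variance
  cancels). The evaluator's structure defaults to naive Bayes — the
  configuration documented for the selection experiments this design
  follows, and roughly 60× cheaper inside a search loop — with TAN
  available. Evaluations are memoized; no subset is ever scored twice.

Tie-breaks are deterministic throughout: equal scores prefer smaller
subsets, then lexicographic attribute order.

## Evaluation

`cross_validated_scores()` learns the structure *per training fold*, scores
each held-out record once, and pools all out-of-fold posteriors into a
single ROC (the convention under which the package's headline AUCs are
defined; per-fold AUCs can be recomputed from the scores). `roc_auc()`
computes the curve at every distinct threshold with the strict
`score > threshold` alert rule, and the AUC twice — trapezoid and
tie-corrected Mann–Whitney — asserting agreement to $10^{-12}$ on every
call.

`incremental_auc()` emulates deployment: a full model per fold, then
held-out records scored with evidence restricted to the top-$m$ attributes
of the gain-ratio ordering, the rest marginalized, for $m$ from `start_m`
to the full count. At full $m$ it reproduces the standard evaluation
*exactly* (same code path), and at $m = 0$ every record receives the single
marginal-prevalence constant, so the AUC is exactly 0.5 — pooling
per-fold prior estimates instead would contaminate a no-information
evaluation with fold artifacts. The default is partial-evidence inference
on one full model; a `retrain` mode that refits a reduced model per $m$ is
provided because the alternative reading is defensible, but observing
attributes one at a time on a deployed model is the primary semantics.
Monotonicity of the incremental curve holds in expectation over seeds, not
per run.

## The synthetic generator

`synthetic_spec()` plants a chain-shaped TAN: class Bernoulli(prevalence),
relevant binary attributes with
$P(\text{high}) = 0.5 + a(2\,pa - 1) + b(2c - 1)$ (defaults $a = 0.3$,
$b = 0.15$; the chain root uses $a + b$, overridable via
`root_class_effect`), a configurable number of them emitted as
state-conditional Gaussians (means 3 sd apart by default, so discretization
has a recoverable planted cut), plus independent noise attributes. The
default mirrors the envelope of the motivating learning base: ~2,000
records, 60 predictors of which 20 continuous, prevalence 0.15 — the
prevalence is a stand-in, since the real base's prevalence is not published.
`sample_dataset()` also returns the closed-form Bayes-optimal AUC of the
planted model, by exact enumeration of all latent configurations with
class-conditional weights, which anchors the recovery tests.

What the generator does *not* emulate: real attribute semantics, missing
data patterns, label noise, calibration drift, or correlated noise
attributes. Passing tests therefore demonstrate algorithmic correctness and
statistical behavior at a realistic scale, not clinical performance.

Test problem sizes were chosen for statistical power: the CPT-recovery check
uses a balanced prevalence and a balanced chain root so every parent
configuration holds at least ~850 of the 5,000 records, putting the ±0.03
tolerance at ≥ 2.2 standard errors per entry.

## Numerical and design choices

* The TAN root is the first predictor in table column order; MST ties break
  toward the lexicographically smallest index pair. The root choice affects
  only edge directions, not the undirected tree or the fitted likelihood —
  a test asserts equal posteriors for two rootings under ML fits.
* K2's default node order is the table column order, with a seeded random
  order available; determinism is preferred to an unspecified shuffle.
* The two pipeline stage orders (discretize-then-select, the recommended
  default, and select-then-discretize) are both supported. Because the
  discretization criterion is per-attribute, the learned cuts are identical
  either way; the orders differ only in which view the selection stage sees,
  and the pipeline records both for comparison.
* All randomness flows from one root seed, expanded deterministically per
  stage; reports serialize without timestamps so reruns are byte-identical.
* Model JSON stores probabilities as `%.17g` strings, which round-trip IEEE
  doubles bit exact.
* The cutoff rule is stated as distance to the corner (0 false-positive
  rate, sensitivity 1); the squared-distance form
  $(1-\text{sens})^2 + (1-\text{spec})^2$ is the geometric reading of that
  statement, and is what the package implements.

## Known limitations

* **Wrapper selection optimism.** A wrapper that maximizes a cross-validated
  AUC estimate inherits that estimate's sampling noise (~0.01 at
  $n = 2000$ with 300 positives). Maximizing over many irrelevant candidate
  attributes reliably finds a spurious improvement of +0.001 to +0.006 — the
  winner's curse — so best-first and genetic wrappers retain noise
  attributes unless classes are nearly separable. The filters (CFS,
  gain-ratio) do not optimize a noisy objective over single additions the
  same way and cleanly exclude planted noise in simulation. Practitioners
  wanting parsimonious wrapper subsets should raise the fold count, demand a
  minimum improvement, or cross-check against a filter; the package keeps
  the searches faithful to their classical definitions instead of adding an
  ad hoc penalty.
* Scores under partial evidence multiply raw probabilities; with hundreds of
  predictors this would underflow (log-space message passing would be the
  fix), but at the target scale (≤ ~60 predictors) the smallest products are
  far above the double-precision floor.
* Missing predictor values are rejected at load time by default; the opt-in
  path (`allow_missing = TRUE`) handles them only at inference time, by
  marginalization. No imputation is provided.
* No calibration assessment, AUC confidence intervals or decision-curve
  analysis; the evaluation surface is ROC/AUC plus the minimum-distance
  cutoff.
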