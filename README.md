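# riskbn

Bayesian-network risk prediction for tabular clinical data.

`riskbn` builds an autonomous early-warning model from a rectangular table of
patient records with one binary outcome — the motivating use case is
predicting exacerbations in chronic obstructive pulmonary disease (COPD)
patients from mixed demographic, symptom and spirometry attributes, without
asking pneumologists to hand-specify dependencies. Nothing in the toolkit is
specific to lungs: any binary-outcome table with mixed continuous/discrete
predictors fits.

The pipeline has four learned stages:

1. **Supervised discretization** — each continuous predictor is cut by the
   Fayyad–Irani minimum description length criterion: recursively pick the
   boundary cut maximizing the class-information gain
   *Gain = Ent(S) − (N₁/N)Ent(S₁) − (N₂/N)Ent(S₂)* and keep it iff
   *Gain > log₂(N−1)/N + Δ/N*, with
   *Δ = log₂(3^c − 2) − [c·Ent(S) − c₁·Ent(S₁) − c₂·Ent(S₂)]*.
2. **Relevant-attribute selection** — filters (gain-ratio ranking with the
   half-maximum threshold α = max(GainRatio)/2; correlation-based feature
   selection with Hall's merit *k·r̄_zc / √(k + k(k−1)·r̄_ii)*) or wrappers
   (best-first and genetic search scored by the classifier's cross-validated
   AUC).
3. **Bayesian-network classifier** — tree-augmented naive Bayes (TAN: the
   maximum spanning tree on conditional mutual information *I(X;Y|C)*, plus
   the class as a parent of every predictor) or K2 (greedy parent search
   under a node order, scored by the Cooper–Herskovits marginal likelihood
   Σⱼ[lnΓ(r) − lnΓ(Nⱼ+r) + Σₖ lnΓ(Nⱼₖ+1)]). Inference is exact, by variable
   elimination, and works under *partial* evidence: unobserved symptoms are
   marginalized out of P(V₁,…,Vₙ) = ∏ᵢ P(Vᵢ | Pa(Vᵢ)).
4. **Evaluation and deployment ordering** — stratified 10-fold
   cross-validated ROC/AUC, an alert cutoff at the ROC point nearest the
   (specificity 1, sensitivity 1) corner, and a gain-ratio ordering of the
   selected attributes so that observing symptoms one at a time, most
   discriminative first, raises the AUC as fast as possible
   (`incremental_auc()`).

A seeded synthetic-data generator (`synthetic_spec()` / `sample_dataset()`)
plants a TAN-structured model with Gaussian emissions and pure-noise
attributes at the scale of a real learning base (~2,000 records, 60 mixed
predictors, minority prevalence 0.15), and reports the closed-form
Bayes-optimal AUC of the planted model, so every stage can be validated
end to end without any external data.

## Worked example

```r
library(riskbn)

spec <- synthetic_spec(n = 2000, seed = 7)   # 60 predictors, 20 continuous
ds   <- sample_dataset(spec)
ds$table
#> <risk_table> 2000 records, 60 predictors (20 continuous, 40 discrete), class 'outcome'
#>   positive ('1') prevalence: 0.149

report <- run_pipeline(pipeline_config(
  input = ds$table, selection = "wrapper-bestfirst",
  structure = "tan", seed = 42))
report
#> <pipeline_report>
#>   selected attributes (23): X01, X02, X03, X06, X07, X08, Z17, Z18, ...
#>   cross-validated AUC: 0.9896   cutoff: 0.2151
#>   incremental AUC (m = 8..23): 0.990 0.989 0.989 0.990 0.989 ...

head(as.data.frame(report$ranking), 3)
#>   attribute      gain split_info gain_ratio
#> 1       X01 0.3996549  0.7025163  0.5688906
#> 2       X02 0.3495285  0.7546516  0.4631653
#> 3       X03 0.2938512  0.7674044  0.3829158
```

Reading the output: the wrapper kept 23 of 60 attributes, including all
planted signal attributes `X01`–`X08` that survive discretization (wrapper
searches also retain some noise `Z*` attributes — an inherent optimism of
maximizing a cross-validated score; see the methods vignette). The pooled
out-of-fold AUC of the TAN classifier is 0.9896, close to the planted
model's Bayes-optimal 0.9922. An alert fires when the posterior
exacerbation probability exceeds the selected cutoff 0.215, and observing
only the top 8 attributes of the gain-ratio ordering already yields
AUC ≈ 0.990.

Single stages are exposed directly: `mdl_discretize()` / `apply_scheme()`,
`rank_attributes()` / `gain_ratio_filter()`, `cfs_select()`,
`best_first_search()` / `genetic_search()`, `build_tan()` / `k2_search()` /
`fit_cpts()`, `posterior()` / `posterior_scores()`, `stratified_folds()` /
`cross_validated_scores()` / `roc_auc()` / `select_cutoff()` /
`incremental_auc()`. A thin command-line front end with the same stages as
subcommands ships in `inst/cli/riskbn`.

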