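# autosig

Automated machine learning for binary-outcome, high-dimensional biomedical
tables — omics case/control profiles, clinical cohorts — aimed at
biomarker (biosignature) discovery with honest performance estimates.

Given a samples × features table with one binary outcome column, the
package:

1. derives **meta-features** (sample size, dimensionality, class balance,
   missingness) and generates a space of candidate **configurations** —
   full pipelines of imputation → encoding → standardization → feature
   selection → classification with fixed hyper-parameter values;
2. evaluates every configuration **as an atom** under a stratified,
   R-repeated, K-fold, N-incomplete cross-validation protocol (GCV) whose
   (R, K, N) emulate holdout, K-fold, incomplete and repeated CV, with
   optional early-dropping/early-stopping heuristics and support for
   grouped (repeated-measurement) samples;
3. corrects the winner's estimate for the **winner's curse** by
   bootstrapping the selection step on the pooled out-of-sample
   prediction matrix (**BBC-CV**): for each of B replicates, reselect the
   best configuration on in-bag samples and score it out-of-bag; the mean
   and 2.5/97.5 percentiles give the corrected estimate and 95% CI;
4. can return **multiple statistically equivalent signatures**: a
   forward–backward selection driven by likelihood-ratio
   conditional-independence tests groups interchangeable features into
   equivalence classes whose product enumerates all minimal, equally
   predictive feature subsets;
5. reports **threshold-dependent metrics** (sensitivity, specificity,
   accuracy, F1, …) bootstrap-corrected at 10 quantile thresholds — an
   adjusted ROC with per-point CI "crosses" — plus **permutation variable
   importance** and **ICE curves** for interpretation, and permutation
   tests for comparing analysis runs.

The core estimate is the AUC: the probability that a random case outranks
a random control, ties counted ½ (the scaled Mann–Whitney U).

## Worked example

Everything is testable without downloads: the fixture generator plants
signal, equivalent feature copies, imbalance and missingness.

```r
library(autosig)

fx <- generate_fixture(fixture_spec(
  n = 120, p = 30, k_informative = 3, effect_sizes = c(1.8, 1.4, 1.1),
  duplicate_map = data.frame(source = 1, sd = 0),   # f004 = exact copy of f001
  minority_fraction = 0.4, seed = 42))

res <- run_analysis(fx$dataset, criterion = "feature_selection", seed = 1,
                    bootstraps = 500, verbose = TRUE,
                    overrides = list(R = 2, max_configurations = 200))
print(res)
```

```
data: n=120 p=30 rarest=48 missing=0.0%
configurations generated: 200
protocol: R=2 K=10 N=10
GCV done: 240 predictions, 160 dropped, 0 failed, 2 repeat(s) completed
BBC (B=500): corrected 0.877 [0.780, 0.956], unadjusted 0.907
<autosig_result> 200 configurations, criterion 'feature_selection'
  winner: lasso(pen=0.1)+svm_linear(cost=0.1)
  corrected AUC 0.877 [0.780, 0.956] (unadjusted 0.907)
  signature(s): 1 of size 4
```

The unadjusted estimate (0.907) is the raw pooled CV AUC of the winning
pipeline — optimistic, because it was picked as the best of 200 tries.
The corrected value (0.877) is the BBC estimate of what this *selection
strategy* achieves out of sample, with its 95% CI. 160 of the 200
configurations were abandoned early by the dropping test without changing
the outcome. The signature includes both `f001` and its planted exact
copy `f004`; consistently, permuting `f001` alone barely hurts
performance (`perf_ratio` 0.996) because its equivalent partner
substitutes — exactly the redundancy that multiple-signature selection
(`ses_select()`) makes explicit as equivalence classes.

Winners for all four criteria (performance, interpretability, feature
selection, aggressive feature selection) come from this single run —
`res$winners` — no refitting needed. The final model is refit on all 120
samples; apply it to new data with `apply_model(res$model, new_table)`,
or from the shell via the thin CLI:

```sh
Rscript inst/cli/autosig.R analyze --data table.csv --outcome y --criterion performance --out results/
Rscript inst/cli/autosig.R predict --model results/model.rds --data new.csv
```

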