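---
title: "Methods: automated pipeline search with bias-corrected estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated pipeline search with bias-corrected estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autosig)
```

## The problem

Biomedical tables with a binary outcome — case/control omics profiles,
clinical cohorts — are typically low-sample and high-dimensional
(n in the tens to hundreds, p in the thousands). Analyzing them well
requires choosing preprocessing, feature selection and a classifier with
tuned hyper-parameters, estimating out-of-sample performance without
wasting samples on a holdout set, and not fooling oneself in the process.
Two methodological traps dominate:

* **Leakage**: selecting features on the full table and cross-validating
  only the classifier makes pure noise look predictive. `autosig`
  evaluates every *configuration* — the full recipe of imputation,
  encoding, standardization, feature selection and classification with
  fixed hyper-parameter values — as one indivisible unit, refitted from
  scratch inside every training fold.
* **The winner's curse**: the cross-validated estimate of the *best* of
  hundreds of configurations is optimistic, because the maximum of many
  noisy estimates is biased upward. The package removes this bias by
  bootstrapping the selection step itself (BBC-CV, below).

## The evaluation protocol (GCV)

Configurations are scored under a stratified, R-repeated, K-fold,
N-incomplete cross-validation. Stratification keeps each fold's class mix
within one sample of proportionality; K never exceeds the rarest class
count, so every fold contains both classes. Choosing (R, K, N) emulates
the familiar protocols: (1, 10, 1) is a 10% holdout, (1, K, K) plain
K-fold CV, (R, K, K) repeated CV. `plan_protocol()` picks defaults from
the meta-features: small samples (n < 100) get R = 10 complete repeats
with K = min(rarest class, 20); moderate samples (100–999) get 5 × 10-fold;
large samples (n ≥ 1000) a single 10% holdout. When sample-group
identifiers are present (repeated measurements of one subject), whole
groups are assigned to one fold, since splitting a group across
train/validation overestimates performance.

Two heuristics bound the work. *Early dropping* abandons a configuration
when a one-sided bootstrap test on the pooled out-of-sample predictions
estimates P(AUC_challenger ≥ AUC_incumbent) < `alpha_drop` (default 0.01;
only after ≥ 50 pooled predictions, checked between fold rounds so pooled
counts stay comparable). Two refinements keep the test affordable without
changing its decisions materially: a challenger whose pooled AUC is
within 0.01 of the incumbent's is kept without bootstrapping (the
exceedance probability is trivially near ½), and a surviving challenger
is retested only after its pooled evidence has grown by at least 30%
since its last test (consecutive one-fold increments barely change the
statistic). *Early stopping* ends further repeats when the
winner's bootstrap CI width shrinks by less than 5% relative to the
previous repeat. No standard definition exists for the dropping statistic
or either threshold; both are this package's choices, exposed as
arguments.

## Bias correction (BBC-CV) and threshold metrics

All held-out predictions are pooled into a matrix with one column per
configuration and one row per (sample, repeat) prediction. For each of B
bootstrap replicates (default 1000), *samples* are drawn with replacement
— all repeats of a sample move together, preserving the independence
unit — the best configuration on the in-bag rows is identified, and that
pick is scored on the out-of-bag rows. The mean of the B out-of-bag
values is the corrected point estimate; the 2.5/97.5 percentiles give the
95% CI. The plain pooled estimate of the full-matrix winner is reported
alongside as the *unadjusted* value and is expected to be optimistic on
average. Replicates whose out-of-bag part lacks a class are redrawn (at
most 10·B attempts — a tiny-n safeguard).

Threshold-dependent metrics (sensitivity, specificity, accuracy, balanced
accuracy, precision, F1) are corrected the same way at T = 10 thresholds.
"Ten thresholds dividing the prediction distribution into equal-probability
areas" is ambiguous (10 cuts make 11 regions); we take the 10 interior
quantiles k/(T+1), k = 1..10, of the winner's pooled predictions. Each
threshold's (FPR, TPR) pair carries both CIs — the "cross" on the adjusted
ROC curve. Accuracy-optimal and balanced-accuracy-optimal thresholds are
both reported, since they generally differ.

The final model is the winning configuration refit on *all* samples: it
is the configuration (the model-producing method) whose performance was
estimated, so no samples are lost to estimation, and the reported
performance remains the corrected estimate, never a refit estimate.

## Feature selection and equivalent signatures

`ses_select()` performs forward–backward selection driven by
conditional-independence tests, in the Markov-blanket tradition. The test
is a likelihood-ratio test between nested logistic regressions
(y ~ conditioning set versus y ~ conditioning set + candidate) against a
χ² reference with degrees of freedom equal to the gain in model rank —
the natural choice for a binary outcome with mixed predictors, and
well-calibrated at desk-scale n (verified by simulation in the test
suite). A constant or aliased candidate gains no rank and returns p = 1.

The forward phase admits the candidate with the smallest maximal
p-value below `alpha`, maximizing over conditioning subsets of the
selected set up to size `maxk`. At each admission of a feature f, any
remaining candidate g passing the *symmetric swap test* — g independent
of the outcome given the selected set including f, and f independent
given the selected set with g substituted — joins f's equivalence class:
the two are statistically interchangeable. The backward phase removes
features that become independent given a subset of the others. The result
is a set of equivalence classes whose Cartesian product enumerates all
statistically equivalent minimal signatures (enumeration capped at 10,000;
classes always reported in full). A test budget (default 50,000
independence tests) bounds the cost on huge p; exhaustion returns the
current state with a truncation flag. `lasso_select()` is the
single-signature alternative: the nonzero-coefficient set of an
L1-penalized logistic regression at a fixed penalty.

On null data, a forward selection screening p candidates at level alpha
admits about alpha·p false features per run; the per-feature false
positive rate, not the per-run family-wise rate, is the calibrated
quantity, and that is what the tests assert.

## The configuration space and the four criteria

`generate_space()` crosses the canonical preprocessing chain
(constant removal → mean/mode imputation → one-hot encoding →
standardization, fitted on training folds only) with a selector grid
(none, SES, LASSO) and a classifier grid (baseline majority, decision
tree, ridge logistic, random forest, linear/polynomial/RBF SVM).
Meta-feature rules shape the grids: n < 100 widens the SES significance
grid to {0.01, 0.05, 0.1}; n ≥ 100 adds the LASSO penalty grid;
p > 10,000 drops the polynomial SVM; a rare minority class caps the
forest leaf size. Published hyper-parameter grids for such engines are
not available, so the default grids here are representative, not
replicas, and everything is overridable. An "aggressive" SES variant
(alpha/10, maxk+1) trades performance for smaller signatures. A hard cap
of 5,000 configurations applies deterministic stride thinning.

One run answers all four user criteria without refitting, because
criterion choice only filters the stored per-configuration results:
*performance* admits everything; *interpretability* only humanly
interpretable families (ridge logistic, decision tree, baseline);
*feature selection* requires a selector; *aggressive feature selection*
the aggressive variant. The corrected estimate for a criterion is
computed by running BBC on the admissible columns only, so the bootstrap
reselects exactly the way the criterion selects. Ties break toward fewer
selected features, then the simpler family, then the smaller identifier.

## Interpretation

*Permutation importance* virtually removes a feature by permuting its
column (one fresh permutation per repeat) and re-running the winning
configuration's cross-validation with identical fold partitions and
seeds; the permuted/original pooled-AUC ratio measures added value while
keeping dimensionality and tuned hyper-parameters untouched. The rerun
reproduces the original partitions exactly, so the identity permutation
gives a ratio of exactly 1.

*ICE curves* sweep one feature over its sorted observed values
(subsampled to ≤ 200 grid points) and trace each sample's predicted
probability; the mean over samples is the mean-effect curve, and the
2.5/97.5 percentiles across per-sample lines form the band. Narrow bands
mean the prediction is dominated by that feature. These are what-if
sweeps of a fitted model, not causal statements.

## Comparing runs

`exchange_test()` compares two tools' holdout AUC vectors over common
runs by the median difference, with a null built by exchanging each pair
with probability ½; `signflip_bias_test()` tests whether per-run bias
values (holdout − training estimate) are centered at zero by flipping
signs. Both use 10,000 permutations by default and the add-one correction
(count+1)/(n_perm+1), so p is never exactly zero. A subtlety worth
knowing: the median statistic has no power against an exactly constant
shift (flipping signs of identical values leaves |median| unchanged in
most patterns); it is the variation in real paired performances that
gives the test its power.

## The synthetic generator

`generate_fixture()` draws continuous features as Gaussians (optionally
sharing a within-block factor with correlation ρ), labels from a logistic
model on the informative block with the intercept found by bisection so
the expected minority fraction matches the target to ±0.01, planted
equivalent copies as source + Gaussian noise (sd 0 = exact duplicate),
and completely-at-random missing cells. It emulates the statistical
structure the engine is designed for — planted signal, redundancy,
imbalance, missingness — but deliberately not batch effects, train/test
distribution shift, heavy-tailed intensities or feature-wise missingness
mechanisms; passing tests therefore demonstrate the estimation machinery
is sound, not that any particular real cohort will reach a given AUC.

## Numerical choices and study sizes

Degenerate inputs are handled conservatively: empty signatures fall back
to the class-prior baseline; single-class training folds fall back to the
baseline with a warning; zero-variance columns must be removed before
standardization (error otherwise); SVM probabilities come from a logistic
calibration of the decision values fitted on the training fold (constant
decision values fall back to the prior). Seeds expand deterministically
from one master seed into per-stage seeds, so whole analyses are
bit-reproducible.

The simulation studies behind the package's own validation use n = 100
training samples (from a 200-sample table split in half), p = 200
features, a 101-configuration grid (none + three LASSO penalties crossed
with ridge, tree, linear/RBF SVM and small-forest classifiers, plus the
baseline), a single-repeat 10-fold protocol and B = 500 bootstraps —
sizes chosen so each analysis carries a realistic winner's curse (about
100 diverse candidate pipelines) while a 30-analysis study completes in
minutes on one CPU. The null-case unadjusted winner AUC averages around
0.6 against a true 0.5, and the corrected estimate recovers 0.5 — the
curse and its removal, measured, not assumed.

## Limitations

Binary outcomes from a single table only: no regression, multi-class or
time-to-event support, no multi-omics modality handling, no upstream
omics normalization. The meta-feature rule base is a small, documented
table, not a learned meta-model. LASSO returns a single signature;
multiple-solution LASSO is out of scope. The early-dropping and
early-stopping thresholds, the SES test budget, and the hyper-parameter
grids are package choices where no published specification exists.
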