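---
title: "Immune-status scoring from complete blood counts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-status scoring from complete blood counts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoscore)
```

This vignette documents the model behind the package, the assumptions
it rests on, the tunable parameters and their defaults, the numerical
choices made where the design was open, and what the synthetic-data
tests do and do not establish about real cohorts.

## The scientific problem

Immunosenescence — the age-related decline of immune function — is
continuous and highly variable between individuals: two people of the
same age can have very different immune "physiological ages". The
package turns a routine complete blood count (CBC) into a single
continuous immunity score in (0, 1), oriented so that higher means a
younger-like immune profile, and compares that score against an
age-specific reference to call a subject healthy or sub-healthy.

## Cohort definition: the inflammation filters

The model must be fitted on genuinely healthy adults, because even mild
inflammation shifts leukocyte counts. `apply_health_filters()` retains a
record iff age ∈ [20, 84], procalcitonin ≤ 0.5 ng/mL (strictly greater
rejects; elevated procalcitonin suggests bacterial infection), WBC ∈
[4, 10] ×10⁹/L, NEUT ∈ [2, 7], LYMPH ∈ [0.8, 4], NEUT% ∈ [40, 75] and
LYMPH% ∈ [20, 50]. Retention intervals are closed and the procalcitonin
exclusion strict — the literal reading of the clinical reference ranges.
Each rejection is attributed to the *first* failing rule in the fixed
order age, PCT, WBC, NEUT, LYMPH, NEUT%, LYMPH%, which makes rejection
counts reproducible; the ordering itself is a package decision (the
ranges do not overlap in effect, only in attribution). Records lacking
procalcitonin are retained with a warning by default (`missing_pct =
"reject"` is available), since the screening cohorts this method targets
measure it routinely. When both counts and percentages are supplied and
disagree by more than 0.5 percentage points, counts win: they are the
primary measurement, percentages a derived quantity.

## The 15-index panel

Six absolute counts (WBC, LYMPH, NEUT, MONO, EO, BASO), five
percentages, four ratios (NLR, MLR, ELR, BLR — each inflammation-
sensitive and lymphocyte-denominated). Ratios are always recomputed from
counts; percentages are taken from the record when present and otherwise
derived as 100·count/WBC.

## Three-platform normalization

On the filtered cohort, each index is approximately Gaussian after a log
transform (`fit_index_stats()` reports skewness and excess kurtosis per
index as a diagnostic). With μ and σ the per-index log-scale mean and
standard deviation, the transform for an index that declines with age is

$$\tilde x = \begin{cases}\tfrac12 e^{-(x-\mu)^2/2\sigma^2} & x \le \mu\\
1-\tfrac12 e^{-(x-\mu)^2/2\sigma^2} & x > \mu\end{cases}$$

and the pointwise complement for an index that rises with age. The curve
has three "platforms" — flat regions at 0 and 1 (saturation) and at ½
around the population mean, reflecting the self-regulation capacity of a
healthy immune system — and passes through exactly ½ at x = μ.

Choices worth recording:

* **Direction map.** {WBC, LYMPH, NEUT, LYMPH%} are treated as
  declining with age and the other eleven as rising. This map is a fixed
  constant of the method, not re-estimated per cohort, even though
  NEUT's own age correlation is typically weak;
  `spearman_age_direction()` reports the empirical signs as a diagnostic
  but never overrides the map.
* **Log base.** Natural log. Any fixed base yields identical normalized
  output provided μ and σ are fitted in the same base.
* **σ denominator.** Sample SD (n−1). At cohort scale the difference
  from the MLE is negligible; the choice is recorded for exactness.
* **Zeros.** EO and BASO counts (hence ELR/BLR) can be exactly zero,
  where the log is undefined. Zeros are replaced by half the smallest
  positive observed value of that index; the substitution count is
  warned about and the floor is stored with the statistics so new
  individuals are scored consistently.
* **Open interval.** Far tails underflow to exactly 0 or 1 in double
  precision; outputs are clamped to the largest representable open
  sub-interval of (0, 1) so downstream code can rely on strict bounds.

## EM-fitted Gaussian mixture clustering

Immune status is modelled as a K = 3 full-covariance Gaussian mixture on
the normalized n × 15 matrix, fitted by expectation–maximization: the
E-step computes responsibilities (posterior component memberships), the
M-step the weighted means, maximum-likelihood covariances (1/Nₖ
denominator) and weights πₖ = Nₖ/N. Implementation decisions:

* **Input space.** The normalized matrix (workflow order: normalize,
  then cluster). Clustering the raw log values instead is exposed via
  the pipeline config (`cluster$space = "log"`).
* **Initialization.** k-means++-style seeding of means from the data,
  pooled sample covariance for every component, uniform π; 5 restarts
  by default, best final log-likelihood wins; all restart seeds derive
  from one user seed.
* **Convergence.** Relative log-likelihood change < 10⁻⁶, at most 100
  iterations. Each iteration runs E then M, so the returned parameters
  are exactly the M-step image of the returned responsibilities
  (π equals the responsibility column means to machine precision).
* **Regularization.** A 10⁻⁶ ridge is added to every covariance
  diagonal at each M-step; densities are evaluated via Cholesky
  factors with log-sum-exp normalization, so no likelihood is ever
  formed on the raw scale.
* **Hard labels.** Argmax responsibilities, ties toward the lower
  component index.

Model and K selection use silhouette, Calinski–Harabasz (trace-of-
scatter dispersion, the standard definition) and Davies–Bouldin indices
(`select_clustering()`, with Lloyd k-means via `stats::kmeans` as the
baseline); all three are implemented in the package and verified in the
tests against brute-force O(n²) oracles and the `cluster` package.
Silhouette is computed in row blocks so a 10⁴-subject cohort never
materializes an n × n distance matrix; members of singleton clusters
get s(i) = 0 (the standard convention where the definition is
undefined), and a clustering whose clusters all collapse to points
returns `Inf` for Calinski–Harabasz as a documented sentinel.

The three components are ordered into poor / medium / good by the mean
of their mean vectors — legitimate because normalization orients all 15
axes the same way. The per-age-year membership proportion of each
cluster is correlated with age as a diagnostic: the "good" cluster
should shrink with age, and a warning is raised if its correlation is
not the most negative. The diagnostic is deliberately *not* used for the
ordering itself: membership-proportion trends can rank ambiguously in
cohorts where the middle group dominates, whereas the centroid ordering
is always well defined (exact ties are broken by component index, with
a warning).

## Index weights from ensemble importances

The correlation of each index with immune status is estimated by
training three tree-ensemble classifiers to predict the cluster label
and averaging their normalized feature importances over N repeated
stratified 80/20 splits (default N = 200; the test suite and the
acceptance script use N = 20, which the stability tests show is already
within ±0.02 per index of an independent replicate):

* random forest — 100 trees, impurity (Gini) importance;
* a leaf-wise histogram gradient-boosted ensemble — 31 leaves,
  unlimited depth, learning rate 0.1, 40 rounds, 256 histogram bins
  (grown with xgboost's `lossguide` policy), gain importance;
* depth-wise gradient boosting (xgboost) — max depth 3, learning rate
  0.1, 100 rounds, gain importance.

Each model's importance vector is rescaled to sum to one *before*
averaging — this makes impurity and gain importances commensurable and
guarantees the final weights are non-negative and sum to one. Per-model
means are retained for reporting (`weights_table()`). Tree learners
break split-gain ties by feature position, so importance is only
near-exactly equivariant under feature permutation per run; it is
equivariant in aggregate over repeated splits, which is what the method
uses. Classifier quality (per-group precision/recall/F1, accuracy,
one-vs-rest AUC via the rank statistic, equal to the trapezoidal ROC
area, and optional 10-fold CV accuracies) is reported by
`evaluate_classifiers()`; hyperparameters are fixed constants of the
method, not tuned.

## Score, distribution, age reference

The immunity score is the weighted sum of the 15 normalized values —
a convex combination, hence in (0, 1), equal to ½ for a subject sitting
exactly at the population mean of every index. Score distributions are
reported over the ranges <0.2, 0.2–0.4, 0.4–0.6, 0.6–0.8, 0.8–1 with
half-open-left binning (the published range endpoints overlap, so a
convention must be imposed; [a, b) is used and documented).

The age reference is an ordinary least squares cubic
f(x) = a₃x³ + a₂x² + a₁x + a₀ on all individual (age, score) pairs (not
per-age medians — the scatter-level fit weights ages by their actual
representation). Orders 1–4 are compared by seeded 5-fold
cross-validated MSE, but the cubic is retained *regardless* of the MSE
winner: a quartic can edge out the cubic on in-sample or even CV MSE
while generalizing worse at the age extremes, and the cubic is the
lowest order that captures the plateau–decline shape of the trend. The
full MSE table is always reported so the choice is auditable. A subject
is healthy iff score > f(age) — strictly, so a score exactly on the
curve is sub-healthy. Ages outside the fitted range evaluate with an
extrapolation warning.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method
assumes, so every stage is testable without any download. The five
differential counts are log-normal with

log xᵢ = μᵢ + dᵢ·(age−52)/10 + σᵢ·(q·gᵢ·L + √(1−q²)·εᵢ),

where L ~ N(0,1) is a per-subject latent immune level, gᵢ = +1 for
counts that decline with age and −1 otherwise, and q = 0.4 is the
latent share. WBC is the *sum* of the five counts, and percentages and
ratios are deterministic functions of the counts — sampling them
independently would break the panel invariants the pipeline assumes.
Defaults (baselines 3.5 / 1.9 / 0.42 / 0.12 / 0.03 ×10⁹/L for
NEUT / LYMPH / MONO / EO / BASO; log-sds 0.20 / 0.22 / 0.25 / 0.50 /
0.45; per-decade log drifts −0.025 / −0.09 / +0.035 / +0.09 / +0.055)
were chosen to sit at clinically typical values, to reproduce the fixed
direction map for all 15 derived indexes (LYMPH falls faster than WBC,
so LYMPH% falls and NEUT% rises), and to yield the strongly negative
per-age-median score trend that characterizes real cohorts; they were
fixed once from that calibration. Contaminated records receive
procalcitonin drawn uniformly from 0.6–5 ng/mL (half additionally a
2.5× neutrophilia shift), so they fail the filters by construction and
the generator's truth sidecar (latent level, contamination flag, filter
violation) can be compared record-by-record with the filter output.

What the generator does *not* emulate: platform/batch effects between
analyzers, non-Gaussian log-scale tails, sex-specific levels (only the
sex label is simulated; levels are pooled, as in the method), repeated
measures, and any genuine latent *cluster* structure — the synthetic
immune level is continuous. Consequently the EM-GMM on synthetic
cohorts partitions a continuous cloud (validity indices are
correspondingly weak there), and passing end-to-end tests demonstrates
that the pipeline recovers the age trend and the null correctly, not
that three discrete immune states exist; the clustering machinery
itself is validated separately on labeled Gaussian mixtures with known
parameters.

## Problem sizes and reproducibility

The test suite validates parameter recovery at n = 5000 (10 replicate
seeds), the validity indices against brute-force oracles at n ≤ 50
(20 random instances), and the end-to-end trend on 10⁴-record cohorts;
the acceptance script simulates 10⁴ records and uses N = 20 weight
repeats. These sizes give comfortable statistical resolution for every
assertion made (binomial/rank-correlation standard errors of ~0.01).
Every random draw in the package descends from a single user seed
through a documented stream-splitting helper, so pipelines re-run to
identical artifact digests; the run manifest records the config
snapshot, seeds, per-stage row counts and md5 digests of every output.

## Known limitations

* The poor/medium/good semantics assume the normalization's orientation
  is biologically correct for all 15 indexes; an index whose true age
  direction differed from the fixed map would be scored backwards.
* Weights inherit the instability of impurity/gain importances under
  correlated features (the panel's ratios are correlated with their
  constituent counts by construction); averaging over repeated splits
  mitigates but does not remove this.
* The age reference is a population regression, not a prediction band:
  healthy/sub-healthy is a point comparison against the curve and
  carries no uncertainty statement.
* Scoring new individuals with stored statistics assumes the same
  measurement platform; cross-platform transfer requires refitting the
  normalization statistics.
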