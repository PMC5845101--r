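---
title: "Characterizing missingness and benchmarking imputation in EHR laboratory data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing missingness and benchmarking imputation in EHR laboratory data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrmiss)
```

## The problem

Laboratory results in electronic health records are observed only when a
clinician orders them, and the ordering process is informative: routine
panels go to almost everyone, lipid screening depends on age, sex and BMI,
and specialty assays are ordered precisely because an abnormal value is
suspected. An analysis that ignores this structure — by complete-case
restriction or by naive imputation — inherits its biases. `ehrmiss`
provides the machinery to (a) diagnose which mechanism is plausibly at work
in a lab matrix, and (b) measure, on data where the truth is known, how
each imputation method trades error against calibrated uncertainty.

Because real EHR extracts cannot usually be shared, the package's first
module is a synthetic generator whose ground truth (latent values,
observation probabilities, masks) is retained, so every downstream claim in
this vignette is testable mechanically.

## The synthetic population model

`generate_population()` draws, per patient:

* **Covariates.** Sex (balanced binary), age uniform on 20–88 years at a
  patient-specific anchor date, BMI lognormal with median 27 kg/m² and
  log-sd 0.17 — round numbers typical of an adult outpatient population.
* **Latent laboratory values.** A multivariate normal with a block
  correlation structure: within-panel correlation (default 0.5) and
  cross-panel correlation (default 0.2) over the 28 most common assays
  (CBC, routine chemistry, lipids), plus optional linear effects of the
  standardized covariates on each variable's latent mean. The implied
  correlation matrix is checked for positive definiteness at construction.
* **Marginals.** A monotone inverse Box-Cox map produces skewed positive
  observed scales (exponent 0 = lognormal, 1 = shifted normal; default
  0.5). Because the map is monotone, rank correlations — and every latent
  recovery test — are exact on the latent scale; this is the usual Gaussian
  copula argument.
* **Observation.** Panels, not individual cells, are observed or not
  (labs on one requisition are ordered together), via a logistic model on
  standardized age, sex and BMI (the MAR channel) and optionally on the
  panel's own mean latent value (the MNAR channel). Cell-level dropout can
  be added at a configurable rate. With all slopes zero the generator
  produces MCAR missingness, and a presence-prediction AUROC near 0.5 —
  the package's own diagnostic recovers the design.
* **Events.** Each observed cell receives on average `records_per_patient`
  dated records scattered (sd 180 days) around the anchor date, with small
  latent-scale measurement noise. Dates are integer day offsets from a
  fixed epoch (2000-01-01), avoiding calendar arithmetic ambiguity.

What the generator does **not** emulate: unit heterogeneity and LOINC
mapping noise, inpatient/outpatient mixtures, informative visit timing,
non-Gaussian dependence (tail dependence between assays), and longitudinal
drift within a patient. Tests passing on this generator therefore
demonstrate correctness of the machinery and the qualitative mechanism
contrasts, not performance on any particular health system's data.

## Preprocessing

`filter_records()` applies three rules before any aggregation: events
outside ages 18–90 (ages in exact days/365.25) are dropped; when a death
date is recorded, events in the 365 days before it — and, by extension,
any post-mortem record — are dropped, because ordering intensity and
values both shift near death; variables with results for less than 0.5% of
patients are dropped. `window_and_aggregate()` then takes, per patient,
the median event date, discards events more than 1826 days (5 years) from
it, and uses the median of the remaining values per (patient, variable) —
medians of even counts are midpoints.

`boxcox_z()` normalizes each variable on observed cells only: a shift of
`1e-6 − min` is applied when the minimum is non-positive (the smallest
shift that makes the power transform well defined), the exponent is chosen
by profile maximum likelihood over [−3, 3] with `stats::optimize`
(golden-section / parabolic, tolerance 1e-4), and the result is Z-scored.
The parameters are stored per variable so `invert_boxcox_z()` round-trips
to within 1e-6 relative error. The transform is fit globally rather than
within sex strata; with sex available as a predictor downstream, the
stratification question is deferred to the imputation model.

## Diagnosing the mechanism

Two diagnostics mirror how an analyst decides which variables are safe to
impute. `missingness_ranking()` sorts variables by missingness and traces
the percentage of patients complete for all variables of equal or lower
rank — the elbow of that curve is where adding one more variable collapses
the complete-case pool. `predict_presence()` converts a target variable to
a presence label and trains a 100-tree random forest (via `ranger`) on the
values of all variables *outside* the target's panel — co-members are
excluded because panels are ordered jointly, making their presence
trivially informative. Missing feature cells are mean-filled and flagged
with indicator columns, a choice that keeps the feature matrix complete
without discarding patients. Folds (default 10) are stratified by label so
AUROC is stable at low missingness rates, and per-fold AUROCs are averaged
rather than pooled. AUROC is the normalized Mann–Whitney statistic (ties
count half), which equals the trapezoidal area under the ROC curve.

The qualitative signature, reproduced in the test suite: MCAR amputation
gives AUROC ≈ 0.5; MAR amputation driven by a fully observed column gives
high AUROC (> 0.75 easily); MNAR amputation of the same volume is
predictable only through correlated neighbours, so its AUROC sits between
the two.

## The complete-case benchmark and amputation

Imputation error can only be measured where truth is known, so the
benchmark set is built from complete cases — but complete cases are
systematically younger and healthier than the population. The package
therefore samples patients from the population without replacement and
matches each to the complete case of identical sex with minimal euclidean
distance on age and BMI, both Z-scored on the population (unscaled units
would let age dominate). Matches are drawn with replacement — one complete
case may stand in for several sampled patients — and distance ties break
to the lowest patient id for determinism.

Four amputation mechanisms remove values from the benchmark set while the
truth is retained alongside the mask:

* **MCAR**: every cell independently with probability p; the study grid is
  five levels (10–50%) times ten replicates = 50 datasets.
* **MAR**: choose columns A ≠ B and a quartile of A; rows whose A value
  falls in that quartile lose their B cell with probability 0.5. All
  ordered pairs × 4 quartiles give V(V−1)·4 datasets — 3,024 at 28
  variables.
* **MNAR**: a column loses cells whose own value falls in the chosen
  quartile, with probability 0.5; V·4 = 112 datasets at 28 variables.
* **Realistic**: each benchmark patient copies the missingness pattern of
  their nearest population neighbour (sex-exact, age/BMI distance, self
  excluded), transplanting the empirical missingness structure onto known
  truth.

Quartiles are empirical (type-7 quantiles at 0.25/0.5/0.75) with
boundary ties assigned to the lower quartile; on distinct values this
reproduces exact rank-based assignment. Each grid cell derives its seed by
hashing the master seed with the cell's spec, so grids are reproducible
and order-independent.

## Imputation methods

Eleven methods, one `impute()` dispatcher. Three design points matter:

**Determinism is structural, not accidental.** Mean, median, KNN, the two
low-rank methods, and the two deterministic regression fills initialize
deterministically and contain no random draws, so their m copies are
bitwise identical and their between-imputation error is exactly zero.
Random sampling, Bayesian-regression (norm), pmm, and rf run m independent
seeded chains. This split is what the calibration analysis is designed to
expose.

**Chained equations (FCS).** Missing cells are initialized (stochastic
methods: draws from the observed values; deterministic: column means),
then for each of 10 cycles the incomplete variables are visited in
ascending missingness order and refilled by regressing observed cells on
the allowed predictors' current values. The predictor matrix excludes any
pair with |pairwise-complete r| > 0.85 — on lab panels several assays are
near-linear combinations (hematocrit/hemoglobin, LDL/total cholesterol)
and unpruned designs destabilize pmm. Singular designs fall back to a
ridge penalty of 1e-6 (relative), with a message. The Bayesian draw for
norm and pmm samples from the standard normal–inverse-χ² posterior of the
least-squares fit; pmm computes predicted means for observed and missing
cases under the drawn parameters and imputes each missing case with a
uniformly chosen donor among the d = 5 nearest predicted means, so
imputations stay in the observed support. The rf fill (10 trees) draws a
tree uniformly per missing case and samples an observed value from the
case's terminal node. The `col` method is a single deterministic
column-order sweep from mean initialization; `norm_predict` is the same
deterministic regression iterated in missingness order — both exist
because column-wise deterministic fills are a common baseline distinct in
visit logic. Ten iterations is deliberately conservative; convergence is
not tested formally, but per-iteration mean absolute changes of the
imputed cells are returned for inspection.

**Low-rank completion.** Both variants center per variable on observed
cells, start missing cells at the column mean, and iterate
SVD-shrink-refill until the relative change of the filled cells drops
below 1e-4 (cap 100 iterations; non-convergence sets a warning flag, the
result is still returned). Cold-started, this fixed-point iteration is
prone to stalling in spurious fixed points, so both variants warm-start
with a soft-threshold annealing phase (threshold decaying geometrically
from half the top singular value over 30 steps). After the soft iteration
converges, a debias polish re-runs the hard-truncation iteration at the
effective rank the threshold selected (components above 1% of the largest
thresholded singular value), removing nuclear-norm shrinkage bias; with a
threshold above the top singular value the low-rank part is empty and the
method degrades, exactly, to mean imputation. Default soft threshold is
1/50 of the initial top singular value; default truncation rank is
min(10, min(dim) − 1). KNN uses root-mean-square distance over jointly
observed variables (so rows comparable on few variables are not favored),
k = 5, extending past neighbours that lack the needed variable and
falling back to the column mean when no neighbour carries it.

## Evaluation

`rmse_masked()` scores only the amputed cells, overall or per variable; a
variable with no masked cell is reported as absent (NA), not zero.
`mi_calibration()` computes, per variable, x = mean RMSE of each copy
against the truth and y = mean pairwise RMSE between copies, both on the
masked cells. If the imputation uncertainty is honest, x ≈ y. The summary
statistic is the **mean deviation from unity**, MD = mean over variables
of (x − y): 0 for calibrated methods, equal to mean(x) for deterministic
methods (y ≡ 0), positive for under-dispersed stochastic methods. The
signed-mean definition is one of several possible summaries of the (x, y)
cloud; it is recorded in the evaluation output metadata so downstream
consumers know which was used.

Two closed-form anchors calibrate the scale on standardized Gaussian truth
under MCAR: mean imputation's RMSE tends to the truth sd (1.0), and random
sampling's to √2, since E(X − X′)² = 2σ² for independent draws — the
ceiling any sensible method should beat. The benchmark driver runs the
cartesian product of datasets and methods, isolating failures per cell
(one method's convergence failure should not abort a 3,000-dataset sweep).

## Problem sizes, defaults, and reproducibility

The shipped tests and the acceptance script use populations of 2,000–5,000
patients, benchmark matrices of a few hundred to a few thousand rows, and
m = 5 imputations — sizes at which every statistical claim tested (AUROC
bands, RMSE limits within ±0.05, MD within ±0.1, moment recovery) has
comfortable sampling margin while a full run stays interactive. All
stochastic stages take explicit integer seeds; grids and pipeline stages
derive per-cell seeds by hashing the master seed with a descriptive key,
so results are independent of execution order. The pipeline driver
(`run_pipeline()`) writes every artifact as delimited text with an MD5
manifest; rerunning the same configuration reproduces the manifest
checksums exactly.

## Known limitations

* The generator's correlation structure is block-equicorrelated; real lab
  panels have richer spectra. Latent recovery tests would pass regardless;
  method *rankings* on real data may differ.
* MNAR imputation is evaluated but not modeled: no selection-model or
  pattern-mixture machinery is included, so MNAR results quantify damage,
  not repair.
* The chained-equations engine handles numeric variables only, matching
  the all-numeric laboratory setting.
* `ampute_realistic()` requires every complete case to have a same-sex
  non-self neighbour in the population; tiny or single-sex populations are
  rejected rather than silently mismatched.
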