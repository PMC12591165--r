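---
title: "Methods: cell-type-specific transcriptomic aging clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-specific transcriptomic aging clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-nucleus RNA-seq of an aging/intervention study asks, per cell type:
does a treatment make the transcriptome of aged animals look *younger*?
cellclock answers this with cell-type-specific transcriptomic aging
clocks. The study design it targets is a three-group comparison — young
vehicle-treated (~3 months), aged vehicle-treated (~12 months), and aged
treated animals, five animals per group — with nuclei assigned to
hippocampal-style cell types. A clock is trained per cell type on the
vehicle animals only; its prediction on the treated animals is that
group's "transcriptional age", and a cell type is called rejuvenated when
the treated group is predicted significantly younger than aged vehicle.

## Pseudocells

Single-nucleus profiles are too sparse to regress on directly. Within
each (sample, cell type) stratum we repeatedly draw 15 distinct cells and
sum their raw counts, producing 100 bootstrap "pseudocells" per stratum
by default. Draws are without replacement from a shuffled, depleting
queue; when the queue runs out mid-draw it is refilled with a fresh
shuffle of the whole stratum, and any cell already inside the current
pseudocell is deferred to the front of the queue rather than drawn twice.
This keeps every pseudocell's 15 members distinct while using each cell
either `floor(15 * n_reps / N)` or `ceiling(15 * n_reps / N)` times over
the replicate set — no cell is systematically over- or under-sampled.
Strata with fewer than 15 cells are skipped (a 15-member pseudocell with
distinct members cannot be formed), with a warning.

Aggregation is by *summation* of raw counts rather than averaging: after
the library-size normalization below the two are equivalent, and sums
keep integer counts for inspection. The normalized view used for
regression is `log(1 + 1e4 * count / total)` per pseudocell (natural
log); it is invariant to rescaling a pseudocell's counts, so sum-vs-mean
aggregation cannot affect the fitted clocks. Normalization before
regression is a package choice (the upstream protocol exports raw
counts and leaves this step open); the scale factor is configurable.

## The clock

Each cell type's clock is an elastic-net linear regression
(`glmnet`) of chronological age in months on the standardized normalized
pseudocell expression:

- **Mixing weight** `alpha = 0.5` by default, configurable. The upstream
  literature inherits this choice without stating it, so it is surfaced
  in the configuration and logged rather than hidden.
- **Penalty** `lambda` is chosen as the minimizer of inner
  cross-validated mean squared error along glmnet's descending lambda
  path (the "lambda-min" convention), with 5 inner folds by default and
  fold assignment controlled by the seed. Inner folds are *grouped by
  animal*: pseudocells of one animal never straddle an inner
  train/validation split, otherwise the penalty is selected against
  leaked animal signatures and the clock overfits its training animals
  (with fewer than three training animals the folds fall back to the
  pseudocell level).
- **Features** are genes detected in at least 5% of training pseudocells
  (configurable, off with `min_detect_frac = 0`), centered and scaled on
  the training set; zero-variance genes are dropped. Standardizing makes
  the absolute coefficient a meaningful *variable importance*, and the
  genes with non-zero importance are the clock's **driver genes**.
- Degenerate inputs degrade explicitly: identical pseudocells yield an
  intercept-only model predicting the mean training age; a single
  distinct age label is an error; a single usable feature falls back to
  ordinary least squares (glmnet requires two predictors).

Predictions are affine (`intercept + coefficients . standardized
expression`); a sample's transcriptional age is the arithmetic mean of
its pseudocells' predictions. Genes missing from a prediction set are an
error, never silently zero-filled.

## Leave-pair-out cross-validation

Validation pairs each young vehicle animal with one aged vehicle animal
at random, without replacement: five animals per group give five folds,
each training on the remaining eight vehicle animals and predicting the
held-out pair. Per-fold Pearson correlation over one pair is degenerate
at the sample level (two age values), so the package's primary statistic
is the Pearson R between predicted and chronological age over the
held-out pseudocells *pooled across folds*; per-fold sample-mean
predictions are emitted as diagnostics. Fold structure is asserted on
every run: test pairs partition the vehicle animals and no animal
appears in its own training set. A cell type absent from some fold's
training data is reported as `NA` with a warning rather than failing the
whole run.

## Rejuvenation testing

The clocks used for inference (as opposed to validation) are trained per
cell type on *all ten* vehicle animals, then applied to every sample.
The statistical unit is the per-sample mean predicted age — five values
per group — not the ~100-fold larger pseudocell set, which would
pseudo-replicate the animals. Per cell type we run a one-way ANOVA
across the three groups followed by Tukey's HSD correction on the three
pairwise contrasts, and flag `significant_rejuvenation` when the aged
treated mean is *below* the aged vehicle mean with a Tukey-adjusted
p < 0.05. Note that a direction-gated, Tukey-adjusted specific contrast
is conservative relative to its nominal level under a complete null
(theoretical firing rate ~0.010 at n = 5 per group), which is the price
of family-wise control; the power analyses in the test suite measure
detection under planted effects directly. Chronological training ages
default to 3.0 months (young) and 12 months (aged); when only a range
such as 11–12 months is known, per-sample ages can be supplied
explicitly.

Driver genes are summarized across cell types by exact set arithmetic:
for each threshold k, the genes with non-zero importance in at least k
cell types, optionally restricted to the cell types flagged as
rejuvenated.

## QC preprocessing

Four per-cell metrics are computed: total counts, genes detected,
mitochondrial percentage, and ribosomal percentage (gene sets by mouse
nomenclature prefixes `mt-` / `Rps`/`Rpl`, or supplied explicitly). A
cell is removed when *any* metric falls outside the closed band
[mean − 3 SD, mean + 3 SD]. Three deliberate readings of that rule:

- **Single pass**: means and SDs are computed once on the full input and
  never re-estimated after removal. Re-filtering an already filtered set
  may therefore remove more cells; that is intentional and tested.
- **Sample SD** (n − 1 denominator), the default of mainstream
  statistics stacks; the difference from the population SD is negligible
  at realistic cell numbers but must be fixed to be testable.
- **Union over metrics**: violating any one metric removes the cell.
  Whether the original filters were applied jointly or sequentially is
  not documented upstream; the union is the simplest deterministic
  reading.

Zero-count cells are removed up front with a warning (their percentage
metrics are undefined). The meaningful-PC helper counts components whose
variance fraction *strictly* exceeds the equal-share level 1/(number of
computed PCs); ties do not count, and the rule is invariant to rescaling
the variances.

## The synthetic data generator

The study's raw data are not required anywhere: `simulate_dataset()`
generates the full design with known ground truth. The model is standard
for scRNA-seq counts:

- Gene baselines: log-normal means anchored so an average cell totals
  ~2500 counts; per-cell library factors log-normal with CV 0.3;
  counts negative binomial with size (inverse dispersion) 10.
- Animal-level variability: each sample adds a per-gene Gaussian offset
  (SD 0.1 log-units by default) to every gene's log mean, shared by all
  of its cells. This matters: the rejuvenation test's statistical unit
  is the animal, and without genuine between-animal variance its error
  term would reflect only technical noise, making the ANOVA on sample
  means degenerate. Tests of the count model's closed-form moments set
  this SD to 0 to condition on a single animal.
- Aging programs: per cell type, a planted gene set whose expected log
  mean is `baseline + effect * effective_age`, with effect 0.15
  log-units/month by default — strong, deliberately detectable signal
  for parameter-recovery testing.
- Rejuvenation: treated animals get an *effective age* of
  `aged - r * (aged - young)` months in rejuvenated cell types (r = 0.7
  by default) and the full aged age elsewhere. Recovery of r's
  footprint (the treated group's predicted age) is then a scalar
  parameter-recovery test.
- 5% of genes carry `mt-` names and 5% `Rps`/`Rpl` names so QC metrics
  are exercised; `inject_qc_outliers()` perturbs chosen cells more than
  5 pre-injection SDs from the mean on at least one metric.

What the generator does *not* emulate: ambient RNA, doublets, batch or
chemistry effects, cell-type abundance differences, correlated gene
modules beyond the planted programs, and any spatial/UMAP geometry.
Passing tests therefore demonstrate that the pipeline recovers planted
signal under a clean negative-binomial world — necessary, not
sufficient, for real-data behavior.

## Problem sizes and numerical choices

Test and acceptance runs scale the simulated study so the whole suite
runs on a laptop-class machine: typically 300–500 genes, 15 (structure
and power checks) or 3 (signal-recovery checks) cell types, 25–40 cells
per sample and type, and 15–50 pseudocell replicates per stratum, always
with 5 samples per group and the 15-cell pseudocell size of the design.
The power study for rejuvenation detection uses 100 independent
simulated datasets; the null calibration of the flag uses 500. The
permutation null for cross-validated R deserves care at this design
size: folds are paired by the permuted labels (so training sets keep
the real design's young/aged balance — unbalanced training sets make
null predictions track the training mean, anti-correlated with held-out
labels), and the exchangeable no-animal-effect null is used, because
with animal-level clustering the pooled R has only ~10 effective units
and |R| near 0.3 arises from sampling alone — a fact worth remembering
when judging modest correlations on real data. Pearson R
thresholds (0.8 for signal, 0.3 for permuted labels), the ≥70%
driver-recovery bar, and the ±1.5-month treated-age recovery band are
fixed in the acceptance suite. All randomness flows from a single root
seed split per stage by name (`stage_seed()`), so any stage can be
reproduced in isolation and a rerun of `run_pipeline()` with the same
config is byte-identical.

## Limitations

- Clock hyperparameters beyond the surfaced ones follow glmnet
  conventions; a different alpha or lambda rule changes which genes get
  non-zero importance (ridge-like settings keep more correlated genes).
- With only two distinct training ages, the clock is effectively a
  calibrated two-class discriminant on an age scale; interpolation to
  intermediate ages (the treated group) assumes the planted/observed
  aging programs move monotonically along the same axis.
- The rejuvenation test inherits ANOVA's normality assumption on five
  sample means per group; it is not robust to a single aberrant animal.
- The rejuvenation comparison is structurally anti-conservative: vehicle
  animals are predicted *in sample* (they trained the clock, so their
  predictions absorb animal-level idiosyncrasies and cluster tightly)
  while treated animals are predicted *out of sample*, where regularized
  regression shrinks every prediction slightly toward the training-mean
  age — i.e., downward for aged animals. Both effects push the
  treated-vs-aged-vehicle contrast toward a spurious "younger" call.
  The package quantifies this on synthetic nulls in its test suite
  rather than hiding it: under animal-level variability of 0.1 log-units
  the directed Tukey flag fires in roughly one in five null datasets,
  not one in twenty. An unbiased variant would compare out-of-sample
  (cross-validated) predictions for all groups; the default follows the
  established in-sample design, so treat single-cell-type rejuvenation
  calls with caution and prefer effects that replicate across cell
  types.
- Driver-gene sets are penalization-dependent: membership of correlated
  genes is partly arbitrary, which is why cross-cell-type sharing (k ≥ 2,
  k ≥ 3) rather than single-type membership is the headline summary.
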