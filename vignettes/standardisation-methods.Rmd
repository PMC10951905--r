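---
title: "Confounder-bias standardisation of T1 maps: models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confounder-bias standardisation of T1 maps: models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1stand)
```

## The model

Apparent myocardial T1 is modelled as the value the tissue would show in a
*reference confounding-parameter (CP) environment* plus a CP-induced bias:

$$ v_{\text{apparent}} = v_{\text{reference}} + b(\text{CPs}, v). $$

The bias is estimated by regression on healthy training data. The
dependent variable is the difference between the apparent pixel value and
a *target* value — the mean segmented T1 of training records whose
relevant CPs sit at their reference values — and the independent variables
are the CP values. Standardisation subtracts the estimated bias from every
segmented pixel. Two consequences of this construction are worth keeping
in mind:

* the method makes maps *comparable*, not *accurate*: everything is
  relative to the reference environment, which is itself a convention
  (the default CP set uses age 18, male, a 3T reference scanner and a
  MOLLI 5(3)3 breathhold sequence as references);
* only bias is removed. Imprecision (noise) and genuine biological
  spread remain, so a healthy test cohort keeps a nonzero coefficient of
  variation after perfect standardisation.

Training samples are individual segmented pixels, not per-map means. This
is what makes value binning meaningful: with $k$ bins the regressors (and
the targets) are conditioned on where in the T1 range a pixel falls, so
the bias may depend on the value itself. The number of usable bins is
bounded by the smallest segmented pixel count; more than 10 bins triggers
a warning because per-bin occupancy stops being representative.

## Pipeline parameters

| parameter | values | default / notes |
|---|---|---|
| regression type | `linear`, `lsvr`, `rfr`, `etr` | all at library defaults; the tree ensembles use 1000 trees, which stabilises them without overfitting risk |
| y-type | `absolute` (ms), `relative` (fraction) | absolute shifts all pixels of a map (within a bin) equally; relative scales the shift with the value |
| mode | `individual`, `cascaded`, `ensemble` | see below |
| bins | 1 – min(pixel count) | 1; binning is a fine-tuning step |
| cluster type | 8 algorithms | `equal_distant` when unused |
| CP order | permutation of the CP set | `age, sex, scanner, sequence`; recorded in the model because cascaded results depend on it |
| seed | integer | drives k-means/Gaussian-mixture initialisation and tree fitting; fixed seed gives bit-identical pipelines |

Regressor backends: ordinary least squares for `linear` (stored as plain
coefficients); `e1071::svm` with a linear kernel for `lsvr`; `ranger` for
`rfr` and `etr` (`etr` uses the extra-trees split rule without bootstrap
resampling). Two deliberate deviations from the R libraries' own defaults
keep the backends faithful to the linear-SVR and regression-forest
conventions this method family assumes: the SVR tube width is
$\varepsilon = 0$ (the 0.1 default would swallow relative-scale targets
entirely) with features unscaled (so that constant-feature intercept-only
fits are well defined), and the forests consider all features at each
split (`mtry = p`), the standard choice for regression forests. A
degenerate training response (all values equal) short-circuits to a
constant model for every regression type; this is the exact solution and
avoids SVR's empty-support-vector failure mode.

## Fitting modes

**Individual** fits each CP on the records whose *other* CPs all sit at
reference ("all else held constant" read in its strictest form: equal to
the reference values — the only stratum where targets are defined). This
isolates each CP's effect but uses little data, and any CP value that
never occurs in such a stratum is *uncovered*: it is recorded in the
model, contributes zero bias at application time, and a note is attached
to the result. **Cascaded** fits CPs in order, subtracting each fitted
CP's bias from the working training values before fitting the next, so
stage $k$ can use every record whose *not-yet-fitted* CPs are at
reference; the amount of usable data grows along the cascade, at the cost
of order dependence. **Ensemble** fits one regression per bin on the full
CP vector, with categorical CPs encoded as integer codes in lexicographic
label order (frozen in a codebook). It captures cross-CP structure best
but refuses to standardise a category absent from its codebook — that is
an application error rather than a silent zero, because an integer-coded
regressor would otherwise extrapolate nonsense.

Contracts the mode definitions leave open were fixed as follows. Bin
membership is always assigned from the *apparent* pixel values and frozen
through the cascade, both at fit and at application time, so assignment
is deterministic and identical in both phases. Per-stage targets are
computed from the working (already partially standardised) values of the
records whose concerned CP is at reference. The relative bias is defined
with the apparent value in the denominator, $b = (v - t)/v$, and is
converted back to ms at application as $b \cdot v_{\text{current}}$,
applied sequentially in CP order in the cascade (component $k$ scales the
value already corrected by components $1..k-1$); this keeps the inverse
map single-pass and bounded for $b < 1$. A bin that contains no
reference-matching pixels leaves the target undefined; fitting aborts
with a configuration error rather than imputing. In grid searches over
synthetic cohorts this is the dominant failure mode for large bin counts
— extreme bins are often populated only by strongly shifted (e.g. 1.5T)
pixels — and such settings are flagged `failed` in the report and
excluded from ranking rather than crashing the sweep.

## Binning numerics

One-dimensional clusterings are converted to contiguous half-open
intervals $[lo, hi)$: clusters are ordered by mean, boundaries are the
midpoints between the extreme members of adjacent clusters, and the outer
intervals extend to $\pm\infty$ so assignment is total — values unseen in
training (including at application time) fall into the nearest edge bin.
A value exactly on a boundary joins the upper bin. `equal_distant` places
boundaries at $\min + k(\max-\min)/n$; `equal_size` sorts the values and
splits them into bins whose occupancies differ by at most one. The
agglomerative variants and the equal rules are deterministic; k-means
(10 restarts) and the Gaussian mixture are seeded from the pipeline seed.
All-equal values with more than one bin are a configuration error, since
clusters are undefined.

## Pipeline selection

Settings are ranked by the coefficient of variation of per-map mean T1
over a held-out healthy test set, $\mathrm{COV} = \sigma/\mu$ with the
sample ($n-1$) standard deviation — the COV here is an inter-subject
dispersion estimate. The search is two-step: all 24 combinations of
regression type, y-type and mode at one bin; then the top 3 crossed with
bins 2–10 and all 8 cluster types (216 settings, 240 total). Stage-1 ties
break by enumeration order (regression type, then y-type, then mode) for
reproducibility; failed settings are excluded from the top-3 rather than
imputed. Whether the COV should be taken over maps or over subjects is
ambiguous when subjects contribute several maps; the default is over
maps, with `per_subject = TRUE` averaging within subject first. Bin
partitions depend only on (values, bins, cluster type, seed), so the grid
search caches them across settings.

## Evaluation choices

Summary intervals are two-sided 95% t-based CIs of the mean (the CI
method is this package's choice). Cohort comparisons run Shapiro-Wilk on
every group: if all pass at $\alpha = 0.05$ the route is parametric
(pooled-variance independent t-tests pairwise, ANOVA omnibus), otherwise
nonparametric (Mann-Whitney-U pairwise, Kruskal-Wallis omnibus); a pair
is significant only if both its pairwise and the omnibus p-value are at
or below $\alpha$. A constant group routes to the nonparametric branch
with a warning. No multiple-testing correction is applied beyond this
dual-test rule. The ROC analysis classifies positive at or above the
threshold (disease raises native T1); candidate thresholds are midpoints
between consecutive pooled unique values plus $\pm\infty$, the reported
threshold maximises Youden's $J$ (ties to the lowest threshold, i.e. the
most sensitive of the equally good cutoffs), the AUC is the rank-sum
statistic with ties counted one half, and diagnostic evidence is declared
at sensitivity + specificity ≥ 150%.

## What the synthetic generator does and does not emulate

`generate_cohort()` draws a per-subject base T1 from
$\mathcal{N}(1150, 40^2)$ ms, assigns a CP environment, composes the
injected effects (slope effects first, then multiplicative, then
additive, then the cohort's disease offset), renders an annular phantom
(the mid-ventricular myocardium is an annulus on a short-axis slice) and
adds per-pixel Gaussian noise (default 30 ms). Default effect sizes are
chosen to be clinically plausible: +0.5 ms/year of age, +25 ms for
female sex, a ×0.87 field-strength factor for the 1.5T scanner category
(≈ −150 ms), +35 ms for SASHA, and disease offsets of +50 ms (HCM) and
+200 ms (AMY) over healthy myocardium — magnitudes in the range reported
for clinical cohorts. Three designs cover the fitting modes' data needs:
`random` (independent draws), `oat` (one-at-a-time variation, guaranteeing
the reference environment and every single-CP stratum are populated —
what individual-mode fitting requires) and `paired` (each subject scanned
in every listed environment, cancelling subject-level variation in
effect estimates).

The generator deliberately does **not** simulate MR physics: no
MOLLI/SASHA relaxometry, no heart-rate or breath-hold dependence, no
spatially structured noise, no segmentation error, and effects are
additive/multiplicative without cross-CP interactions. Passing tests
therefore demonstrate that the estimator recovers the biases it assumes,
with realistic magnitudes and noise — not that those assumptions hold in
clinical data.

## Problem sizes and numerical tolerances

The test-suite and acceptance-script cohorts use ring phantoms of ~40–200
pixels and 10–60 subjects; the full 240-setting grid search runs on a
20-subject training and 12-subject test cohort with ~100 pixels per map.
These sizes keep every bias identifiable (paired designs put group-mean
noise below 1 ms) while the whole pipeline remains quick to re-run.
Noise-free oracle checks require agreement to 1e-6 ms; noisy recovery at
30 ms pixel noise with 60 paired subjects is required to land within
±10 ms of the injected category offsets. Determinism is exact: fixed
seeds give bit-identical models, standardisation results and grid
reports, and archives reload to bit-identical behaviour.

## Known limitations

* Uncovered CP values silently pass through (by design, with a note);
  a heavily uncovered training set yields a pipeline that looks trained
  but corrects little.
* Per-bin targets abort on empty reference bins; rich multi-bin settings
  therefore need reference-environment pixels across the whole value
  range, which small or strongly shifted cohorts may not provide.
* The DICOM layer reads single-frame explicit-VR little-endian files
  only; enhanced multi-frame objects and DICOM-SEG masks are out of
  scope, as are registration and segmentation themselves.
* Standardised values inherit the reference environment's accuracy; the
  reference MOLLI variant is known to underestimate true T1, and this
  package makes no attempt to correct that.
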