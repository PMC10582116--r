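---
title: "Whole-brain motor-mapping group analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain motor-mapping group analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`motormap` implements a complete group-level analysis chain for block-design
motor-task fMRI — first-level GLM, fixed-effects run averaging, TFCE
permutation inference, activation-extent and similarity metrics, pairwise
correlation variability statistics, and normalized structural comparisons —
together with a synthetic two-group cohort generator so that every stage can
be exercised, end to end, against known ground truth. This vignette explains
each model, the tunable parameters and their defaults, the numerical
choices, and what the synthetic validation does and does not establish about
real data.

## The first-level model

Each run is modelled voxel-wise by ordinary least squares. For every
movement condition the stimulus boxcar (16-s blocks by default) is built on
an oversampled grid (0.1 s), convolved with the canonical double-gamma
haemodynamic response

$$h(t) \propto \frac{t^{a_1-1}e^{-t/b_1}}{b_1^{a_1}\Gamma(a_1)} -
  \frac{1}{6}\,\frac{t^{a_2-1}e^{-t/b_2}}{b_2^{a_2}\Gamma(a_2)},$$

with peak delay 6 s, undershoot delay 16 s, unit dispersions, and an
undershoot one sixth of the peak — the standard canonical parameterization,
adopted here because it fully specifies a kernel that the analysis chain
named only generically. The kernel is peak-normalized and truncated at 32 s.
The regressor is divided by the kernel's steady-state response (its time
integral), so a sustained block asymptotes to 1 and the simulated percent
signal change at a long-block plateau equals the nominal amplitude.

Each condition contributes a task column and a temporal-derivative column —
the first difference of the task column divided by the TR, which absorbs
small response-latency shifts. The derivative is deliberately *not*
orthogonalized against the task column: that is the plainest reading of
"a temporal derivative applied to the model", and the contrast (the task
column alone, with the derivative as a nuisance) is invariant to the choice
on noise-free designs. An intercept completes the matrix; rank deficiency is
an error that names the collinear columns.

Per condition, `fit_glm()` reports the contrast of parameter estimates
(cope), its variance (varcope = residual variance times the contrast's
quadratic form in \((X'X)^{-1}\)), and \(t = \mathrm{cope}/\sqrt{\mathrm{varcope}}\).
Voxels with an exactly zero residual yield the degenerate conventions
\(t = 0\) when the cope is zero and an infinite sentinel otherwise;
sentinels are excluded pairwise from every downstream correlation.

No prewhitening or autocorrelation correction is applied: the synthetic
noise model is white by construction, and modelling autocorrelation would
exercise machinery the package does not claim. Motion regressors,
slice-timing, and registration are likewise out of scope — all subjects
share one grid, which isolates the statistics under test from resampling
artefacts.

## Fixed-effects run averaging

`fixed_effects_combine()` averages a subject's run-level copes
(\(\bar c = \frac{1}{K}\sum_k c_k\)), propagates only within-run variance
(\(\bar v = \sum_k v_k / K^2\)), and sums degrees of freedom. This is the
literal "average the parameter estimates across the runs" reading — a simple
mean, not an inverse-variance weighted combination — recorded as a
deliberate simplification; for homoscedastic runs the two coincide in
expectation, and the simple mean keeps the arithmetic exactly testable
(K identical runs give the same cope with variance v/K).

## TFCE and max-statistic permutation inference

Threshold-free cluster enhancement integrates cluster support over all
thresholds without committing to a cluster-forming one:

$$\mathrm{TFCE}(p) = \sum_{h = dh,\,2dh,\,\dots}^{h_\max} e(h, p)^{E}\, h^{H}\, dh,$$

where \(e(h,p)\) is the voxel count of the connected component containing
\(p\) in the supra-threshold set \(\{t \ge h\}\). Defaults are the
established volumetric choices \(E = 0.5\), \(H = 2\), 26-connectivity, and
\(dh = h_\max/100\). The implementation processes thresholds from high to
low with an incremental union-find (Rcpp), so components are merged rather
than relabelled per threshold; a brute-force per-threshold relabelling
oracle in the test suite confirms equivalence to well below 0.5%. One
numerical subtlety is worth recording: the top threshold is taken to be
\(h_\max\) itself rather than `n_steps * (h_max/n_steps)`, because the
latter can round one ulp above the maximum and silently drop the entire
top-step contribution. Negative statistic values are enhanced separately on
the negated map and recombined with sign; one-tailed contrasts use the
positive part only.

Family-wise error is controlled by the permutation distribution of the
image-wide maximum TFCE score. One-sample tests flip the signs of subject
effect maps; two-sample tests relabel group membership with group sizes
preserved. When the label space has at most `n_perm` elements it is
enumerated exhaustively and p-values are exact counts (the identity
permutation is part of the enumeration); otherwise permutations are sampled
and the add-one convention \(p = (1 + \#\{M^{*} \ge \mathrm{TFCE}\})/(n_\mathrm{perm}+1)\)
guarantees validity, with ties counted conservatively (\(\ge\)). The add-one
convention also floors p at \(1/(n_\mathrm{perm}+1)\); reported p-value floors
below that are only attainable under exhaustive enumeration. Infinite-t
sentinels are replaced by a large finite constant (1e10) before enhancement
so degenerate voxels dominate rather than poison the arithmetic.

## Activation extent, percent differences, and spatial similarity

Group activation maps are one-sample TFCE results thresholded at
\(\alpha \le 0.05\) FWE. Extent is the significant-voxel count;
between-group differences are expressed as
\((n_B - n_A)/n_A \times 100\) (group B relative to group A, i.e. male
relative to female in the emulated design), reported at 2 decimals with raw
values retained. Spatial similarity correlates, over the in-mask voxels,
the two groups' significance maps encoded as \(1 - p\) with sub-threshold
voxels set to zero — the closest reproducible reading of correlating
"p-value threshold statistical maps"; whether the original tool demeaned
within its mask is not documented, so the demeaned (ordinary Pearson)
choice is stated here rather than asserted as the original's. The full
cross-condition correlation matrix is computed and only the matched-condition
diagonal is kept.

## Variability statistics

Between-subject consistency is the distribution of Pearson correlations of
every unordered pair of subjects' t-maps (\(n(n-1)/2\) pairs per group:
528 + 378 = 906 at the emulated cohort sizes). Within-subject consistency
is the mean correlation over a subject's run pairs (15 comparisons for 6
runs). Groups are compared with a pooled-variance two-sample t-statistic
whose null is generated by relabelling the *pair-level values* — faithful to
the procedure being reimplemented, which treats pair correlations as
independent observations (dof 904). The statistical non-independence of
pairs sharing a subject is documented here, not "fixed": the permutation
test is over pair values because that is the analysis this package
reproduces. The sign convention is group A minus group B, so positive t
means group A (females in the emulated design) is more consistent.
Bonferroni correction uses the exact ratio \(\alpha/m\) with \(m\) the
number of movement conditions (12 at full scale) for the variability family
and \(m = 7\) for the structural family.

The emulated protocol's 13th "rest" row is not reproduced: the generator's
inter-block gaps are the implicit baseline, and a rest regressor would be
collinear with the intercept, so no rest-vs-baseline t-map is defined in
this design. Variability tables therefore carry the movement conditions
only.

## Structural comparisons

Structural metrics (hemispheric cortical thickness, grey-matter volume,
surface area) are normalized per subject as ratios to overall brain volume,
and the seven-comparison family — total volume plus the three normalized
metrics per hemisphere — is tested with the same permutation t-test at
\(\alpha/7\). Normalization removes any common scale: multiplying every raw
metric and brain volume by one constant changes nothing downstream.
Segmentation itself is out of scope; the module's input contract is the
metrics table, which the generator produces from lognormal distributions
(guaranteeing positivity) moment-matched on the raw scale. The default
generative parameters mirror the reported group statistics of the emulated
study — males with ~12% larger brain volume and relatively thinner cortex —
so the default tables reproduce the direction and approximate magnitude of
those effects, including the dof of 59 at the 33 + 28 group sizes.

## The synthetic cohort generator

The generator is the package's ground truth. Its defaults state the
emulated acquisition: 12 movement conditions, 16-s blocks performed twice
per run, 6 runs (192 task seconds per condition), TR 2 s, 2-mm voxels on a
100 x 100 x 72 grid, groups of 33 and 28. Each condition activates a
spherical footprint; per subject the center is displaced by an independent
per-axis Gaussian jitter (truncated by redrawing so footprints stay
in-grid), and group-specific radius, amplitude and jitter SD implement the
hypothesized group differences (extent and between-subject variability) as
*plantable* effects. Noise is i.i.d. Gaussian per voxel-timepoint.
Parameters that the emulated design does not pin down were fixed once at
values a practitioner would call realistic and are not tuned per test:
amplitude 1% signal change at full scale (2-2.5% in small demonstration
grids, where fewer voxels must carry the effect), noise SD 1 scanner unit
against a baseline of 100, rest gaps of 2 s, footprint radii of 4 (group A)
vs 6 (group B) voxels and jitter SDs of 0.5 vs 1.5 voxels as the planted
sex differences.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data — includes temporal autocorrelation and
physiological noise, head motion (notably the higher motion reported for
right-leg movements in the emulated protocol, which is flagged but not
modelled), registration error and anatomical variability beyond center
jitter, vasculature, and non-spherical activation geometry. Conclusions
from the validation suite are about the *statistical machinery* (error
control, recovery of planted effects, arithmetic fidelity), not about
neurobiology.

## Scaled problem sizes

The test and demonstration configurations use a 24^3 grid (or smaller), 2-4
conditions, 1-2 runs, 6-8 subjects per group, and 64-500 permutations for
group maps; the calibration suites use 100-500 replicates on 10^3 grids.
These sizes were chosen as the smallest at which every qualitative effect
of interest (planted extent differences, the between-/within-subject
variability dissociation, FWE calibration) is reliably expressed; the
full-scale profile (5,000 group permutations, 20,000 behavioural
permutations, 33 + 28 subjects) is the documented default of
`pipeline_config()` and `cohort_spec()`.

## Worked example

```{r example}
library(motormap)

cfg <- pipeline_config(
  cohort = demo_cohort_spec(seed = 42L),
  n_perm_group = 500, n_perm_behavioral = 2000,
  seed = 1L, out_dir = "motormap_demo")
bundle <- run_pipeline(cfg)

bundle$activation$table        # per-condition extent + similarity
bundle$between_subject         # pair-level variability tests
bundle$structural              # seven-comparison structural family
```

## Known limitations

- The fixed-effects combination is an unweighted mean; heteroscedastic runs
  would be handled more efficiently by inverse-variance weighting.
- Pair-level permutation tests inherit the dependence of pairs sharing a
  subject; the dof and p-values are those of the reimplemented procedure,
  not of a clustered-inference alternative.
- TFCE p-values are granular at 1/(n_perm+1) (or 1/N under enumeration);
  small permutation counts make the 0.05 threshold coarse.
- The generator's spherical, equal-amplitude footprints are a deliberately
  simple geometry; extent metrics on real data reflect far more complex
  activation shapes.
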