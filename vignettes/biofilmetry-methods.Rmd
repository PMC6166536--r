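---
title: "Methods: models, conventions and design choices in biofilmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in biofilmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmetry)
```

biofilmetry quantifies four kinds of measurements from co-culture
phenotyping experiments on host–epibiont systems: confocal biofilm
morphometrics, growth kinetics, relative gene expression, and
isotope-dilution GC-MS quantification of the AI-2 precursor DPD. This
vignette is the package's account of the underlying models, the conventions
we fixed where instrument software leaves them undocumented, and the limits
of what the synthetic-data tests demonstrate.

## Biofilm morphometrics

### The voxel model

A stack is a 3D grid of non-negative integer intensities with anisotropic
voxel sizes (dx, dy, dz in μm); plane 1 is the substratum. A voxel in plane
k (1-based) is taken to span the height interval [(k−1)·dz, k·dz), so a
biofilm occupying a single plane has thickness dz rather than 0. Confocal
acquisitions for these systems typically use dz between 0.35 and 0.70 μm;
the package accepts any positive spacing and never assumes isotropy.

### Segmentation

Proprietary surface-reconstruction software does not document its
segmentation, so we replace it with the simplest fully stated rule: a
global intensity threshold, occupied iff intensity ≥ t. The default chooses
t by Otsu's criterion — maximize the between-class variance
w0·w1·(μ1−μ0)² of the global histogram over all candidate integer
thresholds, smallest t on ties. An all-constant stack has no separating
threshold and is reported as a degenerate-segmentation error rather than
silently thresholded. A fixed threshold and an optional minimum
6-connected-object-size filter (default off) are available; no despeckling
is applied by default, so every reported number is traceable to the stated
rule.

### The five metrics

For each (x, y) column, the *local biovolume thickness* is
L = (top occupied plane)·dz — substratum to top, internal gaps included —
and the *surface-mask thickness* is M = (occupied plane count)·dz, gaps
excluded, so M ≤ L always. From these:

- maximal thickness: max L (μm);
- biovolume: occupied-voxel count ·dx·dy·dz (μm³);
- compactness: summed fluorescence over occupied voxels / biovolume;
- roughness variance: Σ(L_i − L̄)²/N (μm²);
- continuity ratio: M̄/L̄, in [0, 1].

Roughness is reported in μm², exactly as the variance formula dictates,
although conventional roughness coefficients (e.g. COMSTAT's Ra) are
dimensionless; we implement the formula as defined for this analysis style
rather than normalizing. The divisor N is the number of local thickness
measurements, which raises the question of which columns count. The default
*biomass* policy includes only columns with at least one occupied voxel,
matching the surface-object framing of the rendering tools this replaces
and avoiding dilution of sparse fields by empty background; an include-all
policy is available for fully confluent fields. Undefined metrics — e.g.
compactness or continuity of an empty stack — are reported as `NA`, never
as a silent 0.

### Oracle testing

Every metric is checked, voxel for voxel, against a deliberately naive
triple-loop reference implementation on hundreds of random stacks, and Otsu
against a brute-force scan of all thresholds. On structured synthetic
stacks with foreground/background separation of many noise SDs, thickness
is recovered within one z-step and roughness/continuity exactly on the
quantized heights.

## The synthetic-data generator

Generators are pure functions of their arguments including the seed, and
store analytic ground truth alongside the data. A requested column height h
occupies round(h/dz) planes and the truth records the *quantized* height,
so recovery tests are exact rather than within-half-a-voxel. Gaps must lie
strictly below a column's top plane — a gap at the top would simply lower
the height and contradict the declared truth.

Noise conventions follow standard instrument models where the measurement
chain itself is undocumented: additive Gaussian noise on imaging
intensities (clipped to the bit depth), additive noise on Ct cycles, and
multiplicative (fixed-CV) noise on chromatographic peak areas. Default
imaging means (foreground 200, background 20 counts, SD 8 on an 8-bit
range) give a clean bimodal histogram typical of nucleic-acid-stained
biofilm stacks. What the generator does *not* emulate: optics (no PSF or
axial blur), spatially correlated texture, photobleaching, or the detector
noise characteristics of any particular instrument. Passing recovery tests
therefore demonstrates correctness of the measurement operators, not
robustness to every real-world imaging artifact; segmentation quality on
real stacks remains the user's responsibility to assess.

The growth generator produces lag → log-linear rise → plateau in BCA
units sampled every 30 min over 24 h by default (49 points, the standard
design for these assays), with the rise slope log10(2)/doubling-time. The
qPCR generator encodes a group's fold f as a target-Ct shift of
−log(f)/log(E) cycles at amplification efficiency E, reference Ct constant
across groups; E defaults to 2 (perfect doubling), since the efficiency
handling of the instrument protocols this emulates is not published. The
GC-MS generator splits each analyte area over the two quantifier channels
(m/z 245/348; internal standard 249/352) in a fixed 60/40 ratio; analysis
sums the pair, so the split cancels.

## Growth kinetics

BCA is log10 of the summed object pixel intensities of a frame, so a
doubling of biomass adds log10(2): generation time is log10(2)/m with m the
least-squares slope of BCA against time over the exponential window.
Background correction is pointwise subtraction of a blank curve on the same
time grid.

Window detection is the one genuinely open design point, as plate-reader
vendors do not publish their algorithms. We take the longest run of
consecutive sampling intervals whose local slope exceeds 5% of the maximum
local slope, restricted to the middle 10–90% band of the curve's dynamic
range. The band restriction is what makes the rule robust: without it,
baseline and plateau intervals — whose noisy slopes cross a small threshold
about a third of the time — leak into the run and bias the fit by several
percent. On noiseless curves the detector recovers the doubling time
exactly; at noise of 1% of the dynamic range the median error across seeds
is below 2%. An explicit window always overrides detection, and a curve
with no positive-slope window is flagged as no-growth (`NA` with a warning)
rather than yielding a meaningless number.

## Relative expression

The fold of the target gene versus the reference in group g against a
calibrator group c is E^−((ΔCt_g) − (ΔCt_c)) with ΔCt = Ct_target − Ct_ref.
The default aggregation pairs target and reference wells by replicate index
and averages the per-replicate folds; when replicate counts differ between
genes the group falls back to mean-Ct aggregation, deterministically. The
calibrator's own fold is exactly 1 in the noiseless case; under Ct noise
the mean of its replicate folds is slightly above 1 (Jensen's inequality on
the exponential), which we report honestly rather than forcing to 1. Folds
are invariant to any additive Ct shift applied to both genes. Efficiency is
an explicit parameter in (1, 2] rather than hard-coded at 2, accommodating
Pfaffl-style efficiency correction; no standard-curve efficiency estimation
is included because the assay design this supports does not produce those
data. Rows with non-finite Ct are rejected with a logged count; a group
missing its reference gene is an error, not an imputation.

## DPD quantification

Extracted-ion traces for the analyte channel pair are summed and integrated
trapezoidally within a user-supplied retention-time window (there is no
defensible default window; it depends on the chromatographic method). The
normalized response is (analyte area / internal-standard area) / OD600; the
deuterated internal standard (spiked at 250 ng/mL) cancels injection and
derivatization variability, and the OD600 division — applied to culture
supernatants only, never to cell-free calibration standards — puts samples
on a per-cell-density scale. Calibration is unweighted ordinary least
squares with intercept over at least three distinct standards spanning
25–250 ng/mL (weighting is exposed as an option); concentrations mapping
outside the standard range are flagged as extrapolated rather than
suppressed. Unit conversion uses the identity that ng/mL divided by molar
mass in g/mol is μM directly; the DPD molar mass defaults to 132.12 g/mol
(C5H8O4) and is configurable. Summing the channel pairs before
normalization is equivalent, under proportional fragmentation, to
quantifying per channel and averaging; only summation is implemented.

## Statistics

Group comparisons mirror the conventions of this assay literature: pooled
Student's two-tailed t-test by default ("Student's t-test" taken at its
word; Welch by flag), classical one-way ANOVA across all groups, and
one-to-four asterisks at p < 0.05, 0.01, 0.001, 0.0001 with strict
inequalities — a p exactly at a threshold earns the weaker annotation. No
multiple-testing correction is applied by default, matching per-contrast
reporting practice (Bonferroni is available). ANOVA is reported alongside
the pairwise tests without gating them. Degenerate inputs are handled
explicitly: zero variance everywhere with equal means gives F = 0 / p = 1,
and a zero-variance t-test with unequal means reports the limiting p = 0
with a degeneracy flag. The t-test's type-I error is verified near nominal
(0.05 ± 0.01) under 10,000 null simulations at n = 6 per group, and
F = t² for two groups.

## The pipeline

`pipeline_config()` validates a full configuration (group structure,
geometry, noise levels, contrasts, seed) before any stage runs and
round-trips through YAML; `run_pipeline()` executes all stages, writes one
CSV per stage plus a JSON manifest (package version, seed, config digest),
and is deterministic given the seed — stage seeds are derived from the
master seed, and reruns produce byte-identical tables. Stage logging
reports record counts in and out, including rejected Ct rows.

## Problem sizes used in the test suite

Tests run on stacks from 8×8×8 (oracle equivalence, 200 random stacks) to
64×64×40 voxels (definitional checks), 20–25 seed replicates for the
growth, qPCR and GC-MS recovery studies, and 10,000 null replicates for the
t-test calibration — sizes at which every property under test is already
fully expressed while the whole suite stays fast.

## Known limitations

- Single-channel analysis only: the morphometrics cannot distinguish host
  from epibiont biomass within a stack, and no multi-channel species
  discrimination is attempted.
- The segmentation is global; stacks with strong depth-dependent
  attenuation may need per-experiment thresholds via `method = "fixed"`.
- BCA is consumed as computed (or from supplied object pixel intensities);
  the instrument's image-based object detection is not reimplemented.
- No chromatographic peak-shape modelling, retention-time alignment, or
  isotope-pattern correction: inputs are extracted-ion traces or
  pre-integrated areas.
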