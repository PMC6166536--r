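# biofilmetry

Quantitative phenotyping of bacterial co-culture experiments, built around
host–epibiont biofilm systems such as an *Actinomyces* host carrying an
ultra-small Saccharibacteria epibiont. The package turns the four instrument
outputs of such a study — confocal Z-stacks, plate-reader growth curves,
qPCR Ct tables, and GC-MS extracted-ion peak areas — into the quantities the
biology is argued from, and ships a synthetic-data generator with analytic
ground truth so every stage is testable end to end without any instrument
data.

## What it computes

**Biofilm morphometrics** (COMSTAT-style, from a segmented Z-stack with
voxel sizes dx, dy, dz in μm; a voxel in plane *k*, 1-based, spans
[(k−1)·dz, k·dz)):

- per-column *local biovolume thickness* L_i = (top occupied plane)·dz,
  internal gaps **included**, and *surface-mask thickness*
  M_i = (occupied plane count)·dz, gaps **excluded**;
- **maximal thickness** max_i L_i (μm);
- **biovolume** = (occupied voxels)·dx·dy·dz (μm³);
- **compactness** = total fluorescence over occupied voxels / biovolume;
- **roughness variance** = Σ(L_i − L̄)²/N (μm², population variance; 0 for a
  perfectly uniform slab);
- **continuity ratio** = M̄/L̄ (dimensionless; 1 = no internal gaps).

Segmentation is global Otsu thresholding (or a fixed threshold), documented
and reproducible, in place of proprietary surface rendering.

**Growth kinetics**: BCA = log10 Σ(object pixel intensities); generation
time t_d = log10(2)/m where m is the least-squares slope of BCA vs time over
the detected (or given) exponential window; maximum BCA.

**Relative expression**: ΔΔCt with explicit amplification efficiency E,
fold = E^−(ΔCt_group − ΔCt_calibrator), target vs a 16S-type reference gene.

**DPD (AI-2 precursor) quantification**: trapezoidal areas of the m/z
245+348 (analyte) and 249+352 (deuterated internal standard) extracted-ion
traces; normalized response = (analyte/internal standard)/OD600; external
linear calibration over 25–250 ng/mL; ng/mL ÷ molar mass (132.12 g/mol) = μM.

**Statistics**: two-tailed Student's t-tests (Welch optional), one-way
ANOVA, and the one-to-four-asterisk annotation at p < 0.05 / 0.01 / 0.001 /
0.0001.

## Worked example

```r
library(biofilmetry)

# a synthetic stack: two column populations (10 and 20 um) with a 2-um
# internal gap in every column, realistic imaging noise
sim <- make_structured_stack(
  height_map = matrix(rep(c(10, 20), each = 32), 8, 8),
  gaps = list(list(columns = NULL, from_um = 2, to_um = 4)),
  nz = 50, voxel = c(0.1, 0.1, 0.5), noise_sd = 8, seed = 1)
compute_metrics(sim$stack)
#> <biofilm_metrics>
#>   max thickness:      20 um
#>   biovolume:          8.32 um^3
#>   compactness:        3.998e+04 counts/um^3
#>   roughness variance: 25 um^2
#>   continuity ratio:   0.8667
```

The heights {10, 20} μm have population variance 25 μm²; a 2-μm gap under
every column gives continuity (15−2)/15 ≈ 0.867 on the mean heights — the
segmentation recovers both exactly despite the noise.

```r
growth <- make_growth_series(doubling_time_min = 60, noise_sd = 0.02, seed = 1)
generation_time(growth$curve)
#> 60.7 min (window 180-480 min)

ct <- make_ct_table(c(mono = 1, epibiont_assoc = 4.7), noise_sd = 0.2, seed = 1)
relative_expression(ct$table, calibrator = "mono")
#>            group     fold        sd n
#> 1           mono 1.010163 0.1808970 3
#> 2 epibiont_assoc 4.187030 0.4631187 3

stds <- make_gcms_samples(c(25, 50, 100, 175, 250), noise_cv = 0.02, seed = 2)
cal <- fit_calibration(c(25, 50, 100, 175, 250),
  normalized_response(stds$areas$area_245_348, stds$areas$area_249_352))
smp <- make_gcms_samples(145, od600 = 1, noise_cv = 0.02, seed = 3)
quantify_dpd(normalized_response(smp$areas$area_245_348,
                                 smp$areas$area_249_352, 1), cal)
#>   conc_ng_ml conc_uM extrapolated
#> 1   144.9409 1.09704        FALSE
```

A true 60-min doubling time is recovered to ~1%, a 4.7-fold induction to
~11% at 0.2-cycle Ct noise, and a 145 ng/mL (≈1.1 μM) supernatant DPD spike
to 0.04% — each against the generator's known truth.

`run_pipeline(demo_config(seed = 1))` chains all stages on a four-condition
synthetic design (host alone, host + epibiont, receptor and synthase
deletion co-cultures), writing per-stage CSVs, pairwise contrasts with
asterisks, and a JSON run manifest.

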