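# renalmri

Multiparametric renal MRI analysis in R: voxelwise quantitative mapping
(T1, T2*/R2*, ADC/IVIM, ASL perfusion), T1-histogram cortex/medulla
segmentation, phase-contrast flow with volume-normalised total perfusion,
and test–retest repeatability statistics — exercised end-to-end on a
bundled synthetic kidney phantom with known ground truth.

## Who this is for

Renal MRI produces several quantitative maps per session — perfusion from
arterial spin labelling (ASL), longitudinal relaxation time T1,
effective transverse relaxation T2* (BOLD), and diffusion parameters —
that together characterise kidney structure, haemodynamics and
oxygenation. This package implements the complete analysis chain for
such a protocol for researchers who need reproducible, scriptable map
fitting and region summaries, plus a digital phantom to validate every
stage against known truth.

## The models

All fits are voxelwise:

- **Inversion recovery T1**: `S(TI) = S0 (1 − 2 e^(−TI/T1))`, nonlinear
  least squares with the amplitude profiled out; optional magnitude mode
  with polarity restoration.
- **Multi-echo T2\***: `S(TE) = S0 e^(−TE/T2*)`, log-linear fit with
  optional amplitude-squared weights; `R2* = 1/T2*` reported in 1/s.
- **Diffusion**: mono-exponential `S(b) = S0 e^(−b·ADC)` (log-linear),
  and the bi-exponential IVIM model
  `S(b) = S0 (fp e^(−b·D*) + (1 − fp) e^(−b·D))` by the segmented
  three-step fit (D from b > 200 s/mm², fp from the zero intercept,
  D* with D and fp fixed).
- **ASL perfusion**: control-minus-label differences with integer-voxel
  motion QC (pairs moving > 1 voxel are excluded), averaged into ΔM,
  then inverted through the single-compartment kinetic model
  `ΔM = 2 M0 (f/λ) (e^(−PLD/T1app) − e^(−PLD/T1blood)) / (1/T1blood − 1/T1app)`
  with `1/T1app = 1/T1 + f/λ`, solved per voxel by fixed-point iteration.
- **Segmentation**: a two-component Gaussian mixture on the within-kidney
  T1 histogram (20 ms bins); the lower-T1 component is cortex. Any map is
  summarised per tissue by the mode and FWHM of a Gaussian fitted to its
  histogram (`FWHM = 2√(2 ln 2) σ`).
- **Flow**: per-cardiac-phase ROI flow from phase-contrast velocity
  images, bulk flow in ml/min, and total perfusion = flow / kidney
  volume × 100 (ml/min/100 ml).
- **Repeatability**: intra-subject coefficient of variation
  (sd/mean per subject) and ICC(A,k) — two-way random effects, absolute
  agreement, average measures.

## Worked example

```r
library(renalmri)

geom <- make_geometry(c(64, 64, 5), voxel_size = c(3, 3, 5))
ir   <- simulate_ir_series(geom)              # 13 TIs, 200–1500 ms
t1   <- fit_t1(ir, mask = geom$masks$kidney)
seg  <- segment_cortex_medulla(t1$t1, geom$masks$kidney, bin_width = 20)
attr(seg, "mixture")$mu
#> [1] 1367 1655
```

The two mixture means are the cortex and medulla T1 (ms) — on the
noiseless phantom they equal the generating tissue values exactly.
Adding the perfusion stage:

```r
aslp <- asl_model_params(pld = 1.8, field_strength = 3)  # T1,blood 1.55 s
asl  <- simulate_asl_series(geom, params = aslp, n_pairs = 4)
dm   <- compute_delta_m(asl$series)
ctrl <- which(asl$series$encoding$type == "control")
m0   <- parameter_map(array(apply(asl$series$data[,,,ctrl], 1:3, mean),
                            dim(geom$labels)), "M0", "a.u.", geom$voxel_size)
f    <- quantify_perfusion(dm$delta_m, m0, t1$t1, aslp)
median(f$data[geom$masks$cortex])
#> [1] 255
```

i.e. cortical perfusion in ml/100 g/min, recovered from the simulated
difference signal to within 0.1% of the generating truth (255).

The full phantom → fits → segmentation → summaries → repeatability chain
is one call: `run_pipeline(default_pipeline_config(n_subjects = 3,
n_sessions = 2, seed = 1), out_dir = "out/")` writes the parameter maps
(NIfTI + JSON sidecars), one tidy CSV of per-tissue mode/FWHM summaries,
motion-QC JSON, and per-quantity CoV/ICC JSON.

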