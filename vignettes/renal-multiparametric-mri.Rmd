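---
title: "Methods: multiparametric renal MRI mapping and its phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric renal MRI mapping and its phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the signal models
it fits, the conventions and parameter defaults it adopts, what the
synthetic kidney phantom does and does not emulate, and the numerical
choices behind each fitting routine. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The measurement models

All fitting is voxelwise on a common grid; a voxel that cannot be fitted
(no signal, non-convergence, out-of-range estimate) is encoded `NA` and
excluded from every downstream histogram — never silently zeroed.

### Inversion-recovery T1

The signed recovery signal is `S(TI) = S0 (1 − 2 e^(−TI/T1))`. The
default encoding is the 13 inversion times 200–1300 ms plus 1500 ms. For
fixed T1, S0 enters linearly, so `fit_t1()` profiles the amplitude out
and minimises the residual over T1 alone: a 40-point log-spaced coarse
grid over the admissible range followed by local refinement
(`optimize`, tolerance 1e-4 ms). The coarse grid guards against local
minima; the profiled objective is smooth in T1.

Magnitude images lose the sign of the early-TI points. In magnitude
mode every candidate zero-crossing position is tried — the k earliest
TIs negated, k = 0..13 — and the sign assignment with the lowest
residual wins. Fits with non-positive restored amplitude are discarded.

Estimates outside 100–5000 ms are flagged `NA`. These physiological
bounds exist to keep background and partial-volume voxels from
contaminating the T1 histogram that drives segmentation. Whether the
data are "true" (spin-echo EPI readout) or "apparent" (balanced
gradient-echo readout) T1 is a property of the acquisition, not a
fitting branch: the same model is fitted either way.

### Multi-echo T2*/R2*

The decay `S(TE) = S0 e^(−TE/T2*)` is fitted as a linear regression of
`ln S` on TE (default encoding: 12 echoes, 5 ms first echo, 3 ms
spacing). Non-positive samples are excluded from the log; a voxel needs
at least three usable echoes. The weighted mode uses per-echo weights
proportional to the squared signal amplitude — the first-order error
propagation of the log transform, under which late, noise-dominated
echoes carry little information. "Weighted" is not further specified by
the protocol this package operationalises, so amplitude-squared
weighting is this module's documented interpretation.

The weighting is a bias–variance trade: on simulated magnitude data at
SNR 20 (the medulla-like regime exercised in the test suite) the
weighted fit carries a somewhat larger positive bias than the
unweighted fit — weights computed from noisy amplitudes correlate with
the noise — but a smaller variance, and a smaller total (RMS) error.
The test suite asserts the RMSE ordering; both estimators stay within a
few percent of truth there. R2* is reported in 1/s as `1000/T2*` (T2*
in ms) and is by construction the exact elementwise reciprocal.

### Diffusion: ADC and segmented IVIM

The mono-exponential `S(b) = S0 e^(−b·ADC)` is fitted log-linearly over
a configurable b-range (default: all frames; standard encoding 0, 5,
10, 20, 30, 50, 100, 200, 300, 400, 500 s/mm²). Because capillary
pseudodiffusion decays within the lowest b-values, an ADC fitted on
b ≤ 100 exceeds one fitted over the full range — a property the tests
verify rather than a defect.

The bi-exponential intravoxel incoherent motion model
`S(b) = S0 (fp e^(−b·D*) + (1 − fp) e^(−b·D))` is fitted by the
standard segmented procedure: (1) D and intercept I from a log-linear
fit over b strictly greater than 200 s/mm² (frames 300/400/500 of the
default set — "greater than" is read strictly, and the threshold is a
parameter); (2) `fp = 1 − I/S(0)` with S(0) the measured b = 0 signal;
(3) D* from a one-parameter least-squares fit over all b with D and fp
held fixed.

Two consequences are worth stating plainly. First, the step-1
assumption — pseudodiffusion fully decayed above the threshold — is
only approximate at D* ≈ 10.7 × 10⁻³ mm²/s: at b = 300 the
pseudodiffusion term still contributes ~9% of the tissue term. The
resulting bias is deterministic and the unit tests freeze it exactly
(for cortex-like truth D = 1.7, fp = 0.28, D* = 10.7 × 10⁻³: segmented
D = 1.8074 × 10⁻³ and fp = 0.2381, versus a full three-parameter
nonlinear fit that recovers truth to machine precision). Second, the D*
likelihood is nearly flat once `b·D*` is large; the 1D search therefore
runs on a 60-point log grid over [D, 0.5] mm²/s before local
refinement. fp estimates outside [0, 1) are clamped and flagged rather
than rejected, keeping the maps dense for histogram analysis.

### ASL perfusion

Each label/control pair yields a difference image (control − label).
Pair motion is estimated as an integer in-plane translation of the
pair's control frame against the first control frame, via the circular
cross-correlation peak of slice-summed images; pairs moving more than
the threshold (default 1 voxel, matching the integer granularity of the
exclusion rule) are excluded, the rest averaged (mean, not median) into
a single ΔM map. Exclusion — not realignment — is the implemented
policy; the report lists every shift so a caller can realign upstream
if preferred.

Quantification inverts the single-compartment kinetic model

    ΔM = 2 M0 (f/λ) · (e^(−PLD/T1app) − e^(−PLD/T1blood)) / (1/T1blood − 1/T1app),
    1/T1app = 1/T1 + f/λ

per voxel. Defaults: PLD 1.8 s, λ = 0.8 ml/g, blood T1 1.55 s at 3 T
and 1.36 s at 1.5 T. Perfusion is carried internally in ml/g/s and
reported in ml/100 g/min (factor 6000). Because f appears on both sides
(through T1app), the scalar equation is solved by fixed-point
iteration from the explicit solution with T1app = T1, to a relative
tolerance of 1e-6 or 50 iterations; the removable singularity at
T1app = T1blood is replaced by its analytic limit
`PLD·e^(−PLD/T1blood)`. The no-iteration single pass is exposed as an
option (`iterate = FALSE`); its error grows monotonically with
perfusion — about 2% at f ≈ 100 ml/100 g/min and several times that at
cortical rates, as the property tests measure — so the converged solver
is the default. Negative ΔM produces negative f, preserved and flagged:
clamping would bias tissue means upward.

No transit-delay correction is applied. Short-PLD arrival-time series
are accepted as input but the kinetic model contains no arrival-time
term; this is a known limitation, most relevant in disease where
arrival is delayed.

### Segmentation and histogram summaries

Within a whole-kidney mask the T1 distribution is bimodal — cortex T1
is consistently shorter than medulla T1 at both field strengths, in
health and in chronic kidney disease — so a two-component Gaussian
mixture (unequal variances) is fitted to the within-mask T1 values and
each voxel is assigned to the component with the higher posterior. The
lower-mean component is cortex by physiology. EM is seeded from a
deterministic quantile-based k-means split (centres at the 10th and
90th percentiles): the default agglomerative initialisation of the
mixture fitter can settle on a one-mode-plus-wide-outlier local optimum
on tightly peaked bimodal maps, which the k-means seed avoids. On
noiseless maps the within-class variance is zero and EM degenerates;
the k-means hard split is then exact and is used directly. If the
fitted modes are closer than two histogram bins (default bin 20 ms) or
either component holds under 5% of the voxels, the map is declared "not
bimodal" and an error is raised rather than returning arbitrary masks.

Per-tissue summaries fit a Gaussian curve `A e^(−(x−μ)²/2σ²)` to the
bin counts of the masked histogram by least squares (Levenberg–
Marquardt), reporting the mode μ and `FWHM = 2√(2 ln 2)·σ ≈ 2.355σ`.
Fitting the curve to the histogram — not taking the sample mean and sd —
de-weights outlying voxels and partial-volume tails; the EM-on-values
route is deliberately reserved for segmentation, where per-voxel
posteriors are needed. Bin widths are per-quantity configuration (20 ms
for T1, with defaults scaled to each map's dynamic range otherwise,
1/25 of the observed range when unspecified). At least 50 finite voxels
are required; degenerate (constant) inputs raise.

Kidney volume is the voxel count times the voxel volume, summed across
slices; connected components under 26-connectivity give per-kidney
volumes. Cortex/medulla masks are validated structurally: disjoint, and
contained in the kidney mask.

### Flow and total perfusion

Phase-contrast velocity images (cm/s, already reconstructed; the
phase-to-velocity conversion is the scanner's) are summarised over a
static lumen ROI: per cardiac phase, flow is Σ velocity × in-plane
voxel area (1 cm/s over 1 mm² = 0.6 ml/min), and bulk flow is the mean
over phases, reported in ml/min. Total perfusion divides bulk flow by
the kidney volume it supplies, × 100 (ml/min/100 ml). Flow is exactly
linear in velocity and additive over disjoint ROI partitions — both
asserted to machine precision in the tests.

### Repeatability statistics

The intra-subject coefficient of variation is the per-subject sample sd
across sessions divided by the subject mean (×100), summarised across
subjects as mean ± sd. Subjects may contribute different session counts
(each needs ≥ 2); a zero subject mean is an error, not an `NA`.

The ICC convention is fixed to McGraw–Wong ICC(A,k): two-way random
effects, absolute agreement, average measures —
`(MSR − MSE) / (MSR + (MSC − MSE)/n)` from the two-way ANOVA mean
squares. A complete table is required; subjects with missing sessions
must be dropped by the caller (the pipeline logs and drops them), since
silent imputation would overstate agreement. Under the generating model
`value(i,j) = μ + b_i + w_ij` the population value is
`σ_b²/(σ_b² + σ_w²/k)`, and the estimator converges to it as the
cohort grows — verified at n = 200, k = 3 against the closed form
(which at σ_b = 2σ_w, k = 3 equals 12/13 ≈ 0.923). Group comparisons
(paired t, one-way ANOVA) delegate to the standard R implementations,
with degenerate zero-variance pair sets reported as signed-infinite t
with a flag instead of an error.

## The phantom: what it emulates, and what it does not

`make_geometry()` builds per-slice elliptical kidneys: an outer cortex
rim, an inner medullary core, an unlabelled transition band standing in
for the corticomedullary junction and collecting system, optionally two
kidneys and a vessel disc. Default truth values are the healthy-cohort
means at 3 T (cortex: T1 1367 ms, T2* 49.6 ms, D 1.7 × 10⁻³ mm²/s,
D* 10.7 × 10⁻³ mm²/s, fp 0.28, perfusion 255 ml/100 g/min; medulla: T1
1655 ms, T2* 29.7 ms). Medullary diffusion and perfusion are not
tabulated for this protocol, so physiologically representative values
are fixed once (D 1.6 × 10⁻³, D* 9 × 10⁻³, fp 0.20,
f 100 ml/100 g/min — medullary perfusion well below cortical, as renal
physiology requires). Simulators evaluate the exact forward models
above, so forward-then-fit is an identity on noiseless data — the
backbone of the validation suite.

Noise is Rician (`sqrt((S+n₁)² + n₂²)`, the magnitude-MRI model), with
Gaussian noise available for signed inversion-recovery data. Motion is
an integer in-plane translation applied to whole pairs — matching the
granularity of the >1-voxel exclusion rule. The repeatability generator
draws `μ + b_i + w_ij` per quantity with configurable variance
components; its defaults take between-subject sds from the cohort
table and within-subject sds implied by the published intra-subject
CoVs. No acquisition SNR is published for this protocol, so phantom
noise is a free configuration knob, not a fixed study value.

Deliberately not modelled: respiratory motion curves, k-space and
pulse-sequence effects, B0/B1 inhomogeneity, partial-volume mixing
below the voxel level, arterial transit time, and velocity aliasing
(the flow simulator refuses waveforms beyond venc rather than wrapping
them). Passing tests therefore demonstrate correctness of the analysis
chain under its own assumptions — not robustness to every artefact of
in-vivo acquisition.

## Problem sizes and determinism

The validation phantom is 64 × 64 × 5 voxels at 3 × 3 × 5 mm (≈ 4200
cortex and ≈ 1400 medulla voxels); the end-to-end pipeline default is
48 × 48 × 3 with 20 ASL pairs, sizes at which every stage runs in
seconds while leaving both tissues far above the 50-voxel histogram
minimum. The simulated repeatability cohort uses n = 200 subjects ×
k = 3 sessions for the closed-form ICC comparison and 11 × 3 as the
study-design default. Every stochastic step takes an explicit integer
seed; `run_pipeline()` derives per-subject/session seeds from the
config seed, making reruns byte-identical, and writes a manifest
(config hash, seed, package version) beside its outputs.

## Known limitations

- The segmented IVIM fit inherits the classical threshold bias
  (quantified above); the full nonlinear fit is kept as a test oracle
  only, since on noisy in-vivo data it is less stable than the
  segmented route.
- Motion handling is detection + exclusion at integer-voxel
  granularity; sub-voxel or through-plane motion is invisible to it.
- The kinetic model omits arterial transit delay and labelling
  efficiency.
- Histograms of strongly skewed parameters (D*, fp) are summarised by a
  symmetric Gaussian; the mode remains meaningful, the FWHM less so.
- World-space geometry is out of scope: all stages assume one common
  grid, and the NIfTI affine is not interpreted.
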