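---
title: "Quantitative sodium MRI: simulation, partial-volume regression and the longitudinal outcome battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative sodium MRI: simulation, partial-volume regression and the longitudinal outcome battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natriq)
```

# The scientific problem

Sodium (²³Na) MRI measures the tissue sodium concentration non-invasively,
but at low signal-to-noise and coarse resolution (here a 6 mm nominal voxel).
After a concussion, ionic homeostasis is disturbed, and the apparent total
sodium concentration (aTSC) of grey and white matter is a candidate imaging
biomarker for recovery. Estimating global GM/WM aTSC from such data requires
three steps that this package implements and tests end to end:

1. **Calibration** of the raw magnitude image to millimolar units against two
   internal references: the standard deviation of the background noise
   (mapped to 0 mM) and the vitreous humour of the eyes (assumed 140 mM).
2. **Partial-volume regression**: every brain voxel mixes GM, WM and CSF.
   With tissue volume fractions from a segmented high-resolution proton scan,
   re-gridded to the sodium resolution and convolved with the sodium
   point-spread function (PSF), the observed concentrations form an
   over-determined linear system whose two unknowns are the global GM and WM
   aTSC.
3. **Outcome statistics**: a pre-specified six-hypothesis battery relates
   longitudinal aTSC to three clinical instruments (RPQ, BTACT, GOSE) using
   nonparametric tests with exact permutation p-values at small n.

Because no public dataset accompanies this design, the package ships a
synthetic-data generator for both the image level (digital head phantoms with
known ground truth) and the cohort level (longitudinal subject tables with
configurable effects). Every downstream module is validated against these
known truths.

# The forward model of the sodium acquisition

## Point-spread function

During a centre-out readout of duration $\tau$ (default 36.3 ms, typical for
a three-hub FLORET trajectory), transverse magnetization decays
mono-exponentially with $T_2 = 56$ ms, so k-space is weighted by
$w(k) = \exp(-t(k)/T_2)$ with $t(k)$ growing linearly from 0 at the k-space
centre to $\tau$ at the band edge $k_{max}$. The PSF is the inverse Fourier
transform of this radially symmetric weighting.

Two conventions deserve explanation:

* **$k_{max}$ is a property of the acquisition, not of the grid the kernel is
  sampled on.** We set $k_{max}$ to the Nyquist frequency of the nominal 6 mm
  sodium resolution and sample the same continuous kernel at the simulation
  (2 mm) and sodium (6 mm) grids. This is what makes PSF-smoothing of the
  tissue fractions on the sodium grid counteract the spill-over present in
  the simulated image: both sides discretize one physical kernel.
* **Beyond $k_{max}$ the acquisition time is capped at $\tau$** rather than
  the weight being hard-zeroed. The capped weighting has the correct
  no-decay limit (as $T_2 \to \infty$ the kernel tends to a discrete delta)
  and decomposes the kernel into an identity part plus a band-limited blur,
  which keeps the simulation-side and quantification-side operators nearly
  commutative with block-averaging. The residual inconsistency is what the
  noiseless recovery bias (below) measures.

A Gaussian fallback kernel with matched main-lobe FWHM is available
(`kernel_mode = "gaussian"`) for users who prefer a compact, non-negative
kernel.

```{r psf}
k <- build_psf_kernel(t2_ms = 56, readout_ms = 36.3, voxel_mm = 6)
c(sum = sum(k), fwhm_mm = attr(k, "fwhm_mm"))
```

## Phantom geometry and noise

The digital head is a set of nested ellipsoids — subarachnoid CSF rim,
cortical GM shell, WM core with two ellipsoidal ventricles — plus two
spherical eyes anterior to the brain. Anatomical realism is deliberately
limited: the estimator only ever sees tissue fractions and intensities, so
ellipsoids exercise exactly the same code paths as anatomy. Partial-volume
fractions at tissue boundaries come from sub-voxel supersampling.

The acquisition chain is: convolve the ground-truth concentration field with
the PSF at high resolution, block-average onto the 6 mm grid, scale by a
fixed gain (10 signal units per mM — arbitrary, so that calibration has real
work to do), and add Rician noise (magnitude image; Gaussian optional). The
noise level used by the recovery tests is 5% of the *mean pure-tissue
signal*, defined as gain times the volume-weighted mean of
$(f_{gm} c_{gm} + f_{wm} c_{wm})/(f_{gm}+f_{wm})$ — the signal attributable
to tissue itself, excluding CSF spill, which would otherwise inflate the
reference level by ~20%.

The background noise region is, by convention, 560 voxels taken from the
outer corner of the central slice; on a synthetic field of view a single
slice corner cannot hold 560 signal-free voxels, so the region walks
outward from the corner of the central slice across neighbouring slices,
accepting voxels whose noiseless signal is below 0.1% of the image maximum.

## Eye-reference retention

With a band-limited, T2-apodized PSF, roughly 10% of the vitreous signal
spills out of even a fully interior 6 mm reference voxel. Left uncorrected,
the two-anchor calibration would inflate every concentration by ~11% (a
~4 mM error on GM aTSC). `quantify_volume()` therefore predicts the
*retention* of the reference voxels by pushing the eye mask through the same
forward model (PSF blur, then regridding) and divides the measured eye mean
by it before fitting the calibration line. The two-anchor contract itself is
unchanged: noise SD maps to 0 mM, (corrected) eye mean to 140 mM. Real
acquisitions face the same physics; there the correction would use the
segmented eye mask and the sequence's nominal PSF.

Note the corollary: after retention-corrected calibration the eye ROI itself
reads the PSF-attenuated value, not 140 mM. The plain (uncorrected)
calibration — the convention in which the eye ROI reads exactly 140 mM — is
available via `calibrate_volume()` without a retention argument, and is what
the calibration round-trip test checks.

# Partial-volume regression

On the sodium grid, for every voxel $v$ passing the mask rule
($f_{gm}+f_{wm}+f_{csf} \ge 0.5$ after smoothing, threshold configurable):

$$\mathrm{obs}_v - f_{csf,v}\, c_{CSF} = f_{gm,v}\, a_{GM} + f_{wm,v}\, a_{WM}$$

solved by ordinary least squares for the two unknowns $a_{GM}, a_{WM}$, with
$c_{CSF}$ fixed at 140 mM (a three-unknown mode that estimates CSF freely is
available via `csf_free = TRUE` for sensitivity analysis). The solver
reports the voxel count, residual RMS and the design's condition number, and
rejects rank-deficient designs (e.g. GM fraction proportional to WM fraction
everywhere) with that diagnostic. Fractions are always regridded to the
image grid, never the reverse, and smoothed after regridding; for nested
grids the alternative order is nearly equivalent, and the noiseless recovery
bias quantifies whatever inconsistency remains.

Negative calibrated values are kept (not clamped) inside the regression so
that residuals stay unbiased; clamping is the default only when exporting
concentration maps.

## What the recovery tests show — and what they do not

On the full-size phantom the pipeline recovers the true GM/WM concentrations
to ~0.05 mM without noise (the PSF ordering mismatch) and to a median
absolute error of ~0.7 mM at 5% Rician noise. The dominant noisy-case term
is a systematic one: anchoring the background noise SD to 0 mM shifts all
tissue concentrations down by $(c - 140)\,\sigma_{bg}/(S_{eye}-\sigma_{bg})$,
about −0.8 mM at GM for this noise level. That bias is intrinsic to the
two-anchor convention (it vanishes at the 140 mM anchor, which is why CSF is
unaffected) and is faithfully reproduced rather than corrected. Passing
these tests demonstrates internal consistency of simulation and estimation
under a shared forward model; it does not validate the PSF model against a
real scanner, nor segmentation accuracy, B0/B1 effects or relaxation
weighting, all of which are out of scope.

# The synthetic cohort

`generate_cohort()` draws a longitudinal table mirroring a two-group
concussion study: 27 patients and 21 controls at visit 1 (~22 days from
injury), 20 patients returning for outcomes at visit 2 (~16 weeks; 17 of
them with imaging) and 15 at visit 3 (~60 weeks); controls are measured
once. Patients' visit-1 aTSC sits 2.0 control-SDs below the control mean in
GM and 0.6 in WM, and recovers at 0.04 ± 0.04 mM/day (GM) and
0.01 ± 0.03 mM/day (WM) between visits 1 and 2 — visit-3 imaging does not
exist in the emulated design, so aTSC trajectories stop at visit 2. Control
aTSC SDs (1.8 / 1.6 mM) are chosen so that the ~3.6 mM GM recovery between
visits corresponds to the resolving 2-SD deficit.

A per-patient latent injury factor couples everything: it scales symptom
severity (which decays exponentially with a 250-day time constant), drives
RPQ items up (truncated-Poisson item model on the 0–4 scale), BTACT subtest
z-scores down (−0.5 z per unit severity), and GOSE below 8 past a severity
threshold of 0.8. The coupling strength (default 0.6) ties the aTSC deficit
to that factor; at coupling 0 the generator provably produces aTSC
independent of all outcomes, which is what the null-battery calibration
uses. The defaults produce visit-1 BTACT composite means near −0.35 and
~30% recovered at visit 1, rising over follow-up.

BTACT norms are synthetic placeholders (clearly labelled in
`inst/extdata/btact_norms_synthetic.yaml`): published normative values are
not redistributed, and for simulation only the z-scale matters.

# Nonparametric inference

All tests use midranks for ties and two-sided p-values formed by doubling
the smaller exact tail (capped at 1). Exactness policy:

* **Mann-Whitney U**: exact when $n_1+n_2 \le 20$ without ties, else normal
  approximation with tie and continuity corrections. `exact = "always"`
  enumerates the permutation distribution of the observed midranks even with
  ties.
* **Wilcoxon signed-rank**: zero differences dropped (classic convention,
  not Pratt); exact over all $2^n$ sign patterns when $n \le 20$ without
  ties; same forced-exact option.
* **Spearman**: exact over all $n!$ permutations for $n \le 8$; seeded
  Monte-Carlo permutation (default $10^5$ draws, observed ordering counted
  in numerator and denominator) beyond.

The exact tail counts come from the rank-sum generating function (a
dynamic-programming convolution), which enumerates exactly the same
assignments as brute force without materializing them; half-integer midranks
are doubled to integers first, so tied configurations are also exact. The
test suite checks the resulting p-values against literal brute-force
enumeration over hundreds of fixtures, and against `wilcox.test(exact =
TRUE)` where base R's conventions coincide.

No multiple-comparison correction is applied anywhere, matching the emulated
design; $\alpha$ defaults to 0.05 two-sided.

## Null calibration of the battery

The battery's null check generates effect-free cohorts (no deficit, no
recovery, zero coupling) and pools rejection rates over all comparisons. On
discrete instrument scores exact and tie-corrected tests are mildly
conservative, so the pooled rate is expected slightly below $\alpha$; the
acceptance band (0.03–0.07 pooled over 200 replicates, with a generous
per-comparison bound) was fixed before measurement with that conservatism in
mind. Measured values land near 0.049.

# The six-hypothesis battery

`run_h_battery()` emits the pre-specified comparisons — within-subject
outcome change (H1) and aTSC change (H2) by Wilcoxon signed-rank;
patients-vs-controls aTSC at the second visit with Cohen's d (H3);
cross-sectional (H4), predictive (H5) and rate-coupled (H6) aTSC-outcome
associations by Spearman permutation correlation plus Mann-Whitney
comparisons within GOSE-defined recovery splits. Serial comparisons use only
subjects contributing both visits; comparisons that lack data (an empty
recovery stratum, all-zero differences) are reported as untestable rather
than silently dropped, and verdicts (supported / partially supported /
rejected) count only testable comparisons. "Matched controls" is
implemented as comparison against the full control group: the emulated
design frequency-matched at enrolment, so matching lives in the generator,
not in the test.

```{r battery}
cohort <- generate_cohort(cohort_design(seed = 42))
battery <- run_h_battery(cohort, battery_config(spearman_mc_draws = 2000))
battery
```

# Reproducibility, sizes and limitations

Every stochastic step takes an explicit seed; the full pipeline
(`run_end_to_end()`) is a pure function of its config and writes
byte-identical reports on rerun. Problem sizes were chosen so the whole
validation suite runs in minutes on one CPU: the recovery suite uses 20
phantoms on an 84³ high-resolution grid (~2 s each), type-I checks use 2000
replicates at n = 20 per arm, the power check 500 replicates of the
27-vs-21 design, and the null battery 200 replicate cohorts with 500-draw
Monte-Carlo Spearman p-values.

Known limitations: the PSF model is image-space and isotropic (no k-space
trajectory simulation, no B0/B1 or relaxation-weighting effects); geometry
is ellipsoidal; the eye-retention correction assumes the nominal PSF is the
true one; regional or voxelwise aTSC mapping is out of scope; and the
shipped BTACT norms are synthetic. The two-anchor calibration bias under
noise is reproduced, not corrected — a deliberate fidelity choice.
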