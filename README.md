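# natriq

Quantitative sodium (²³Na) brain MRI analysis in R: digital phantom
simulation with known ground truth, internal-reference calibration to
millimolar units, global grey/white-matter apparent total sodium
concentration (aTSC) by partial-volume linear regression, clinical outcome
instrument scoring (RPQ, BTACT, GOSE), and a pre-specified six-hypothesis
nonparametric battery for longitudinal concussion studies.

## Who this is for

Researchers developing or validating sodium-MRI quantification pipelines,
and analysts of longitudinal mild-TBI outcome studies who need exact
small-sample nonparametric inference. Because sodium MRI datasets are rarely
public, the package is built around a synthetic-data generator at both the
image level (head phantoms) and the cohort level (subject × visit tables
with configurable effects), so the whole chain is testable without any
download.

## The model at the core

Raw sodium signal is calibrated by the two-anchor internal-reference scheme:
the standard deviation of the background noise maps to 0 mM, the vitreous
humour of the eyes to 140 mM. Global tissue concentrations then come from an
over-determined linear system across all brain voxels,

    obs_v − f_csf,v · 140 mM = f_gm,v · aTSC_GM + f_wm,v · aTSC_WM ,

where the GM/WM/CSF volume fractions are re-gridded to the sodium resolution
and convolved with the acquisition point-spread function (mono-exponential
T2 decay with T2 = 56 ms over the readout) so that CSF spill-over is
modelled rather than misattributed to tissue. Ordinary least squares yields
the two unknowns plus fit diagnostics. The outcome battery uses Mann-Whitney
U, matched-pair Wilcoxon signed-rank and Spearman correlation with exact
permutation p-values at small n (Monte-Carlo beyond), plus Cohen's d with
pooled SD.

## Worked example

```r
library(natriq)

## simulate one acquisition with known truth (GM 35, WM 30, CSF 140 mM)
phantom <- generate_phantom(phantom_geometry(), phantom_truth(seed = 1))
raw     <- simulate_acquisition(phantom)
est     <- quantify_volume(raw, phantom$fractions, f_eye = phantom$f_eye)
est
#> Global aTSC: GM 35.007 mM, WM 30.026 mM
#>   1460 voxels, residual RMS 0.370 mM, condition number 1.37

## a longitudinal cohort and the hypothesis battery
cohort  <- generate_cohort(cohort_design(seed = 42))
battery <- run_h_battery(cohort, battery_config(spearman_mc_draws = 2000))
battery
#> Hypothesis battery (alpha = 0.05, two-sided, uncorrected)
#>   H1: partially supported (9/22 comparisons significant)
#>   H2: rejected (0/2 comparisons significant)
#>   H3: partially supported (1/2 comparisons significant)
#>   H4: partially supported (6/8 comparisons significant)
#>   H5: partially supported (5/12 comparisons significant)
#>   H6: rejected (0/10 comparisons significant)
```

The phantom estimate lands within ~0.03 mM of the ground truth without
noise; the battery output lists, per hypothesis, each comparison's test
statistic, permutation p-value, effect size and n. A small end-to-end demo
(simulate → calibrate → quantify → score → test, with reports written as
CSV/JSON) runs via `run_end_to_end(demo_config(seed = 1, out_dir = "out"))`,
or from a shell through the thin CLI at `inst/cli/natriq.R`
(subcommands `simulate`, `calibrate`, `quantify`, `score`, `analyze`,
`demo`).

See the vignette in `vignettes/sodium-quantification.Rmd` for the forward
model, the eye-retention correction, the generator's design parameters and
the package's numerical conventions.

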