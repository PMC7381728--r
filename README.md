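# sonoperf

Quantitative contrast-enhanced ultrasound (qCEUS) perfusion analysis for
monitoring microbubble-mediated **sonopermeation** therapy.

Sonopermeation uses ultrasound-driven microbubble oscillation to transiently
open the tumor vasculature and boost drug delivery. Because microbubble
contrast agents are strictly intravascular, destruction–replenishment imaging
during a constant-rate infusion reads out the vascular effect in real time:
after a high-MI flash-destruction pulse clears the imaging plane, the
ROI-mean contrast intensity replenishes as

```
y(t') = y0 + A * (1 - exp(-beta * t'))
```

with **A** the relative blood volume (RBV, linear a.u.) and **beta** the
reperfusion rate (RR, s⁻¹, proportional to blood flow velocity). Two flash
pulses bracketing the therapy give pre- and post-treatment fits per ROI;
comparing the sonopermeated focal zone against an untreated control ROI
yields control-normalized percent changes in RR and RBV. The package is aimed
at preclinical/translational ultrasound groups who need this analysis chain
reproducible and testable end to end.

## What it does

- **Synthetic phantom generator** (`default_scenario()`, `simulate_tic()`,
  `simulate_sequence()`, `simulate_sweep()`, `simulate_cohort()`): image
  sequences, sweeps and cohorts with exact ground truth — infusion wash-in,
  flash resets, per-region exponential replenishment, treatment effects on
  beta, mean-preserving Rayleigh speckle, optional log compression.
- **Sequence I/O** (`read_sequence()`, `write_sequence()`, `linearize()`,
  `log_compress()`, `read_masks()`, `write_results()`): multi-page TIFF +
  JSON sidecar, label-mask images, YAML protocols, CSV/JSON result tables,
  and linearization of log-compressed video.
- **TIC extraction** (`extract_tic()`, `detect_flash_events()`,
  `segment_replenishment()`): ROI means on linear data, scale-invariant
  flash-pulse detection, replenishment windows re-zeroed at reflow onset.
- **Replenishment fitting** (`fit_replenishment()`, `model_value()`,
  `perfusion_auc()`, `perfusion_index()`): bounded Levenberg–Marquardt with
  analytic Jacobian; RBV, RR, AUC, A·beta.
- **Volumetrics** (`tumor_volume()`, `contrast_blood_volume()`,
  `normalized_rbv()`): slab-model tumor volume (mm³) from stepped 2D sweeps
  and contrast blood volume normalized to it.
- **Treatment inference** (`run_monitoring_pipeline()`, `compare_pre_post()`,
  `control_normalize()`, `cohort_statistics()`): paired pre/post,
  treated-vs-control analysis with paired t and exact Wilcoxon signed-rank
  cohort tests.

## Worked example

Simulate a monitored subject whose treated-ROI reperfusion rate is halved by
therapy (5–10% speckle noise), then run the full pipeline — linearize,
extract TICs, detect the two flash pulses, fit pre/post segments, normalize
against the control ROI:

```r
library(sonoperf)
cfg <- default_scenario(beta_multiplier = 0.5, noise_scale = 0.1, seed = 9)
sim <- simulate_sequence(cfg)
cmp <- run_monitoring_pipeline(sim$sequence, sim$masks)
cmp
#> <treatment_comparison> subject (flashes at 300.0 / 630.0 s)
#>   treated: dRR = -50.0%, dRBV = +0.0%
#>   control: dRR = +0.0%, dRBV = +0.0%
#>   normalized (difference): dRR = -50.0%, dRBV = -0.0%
cmp$fits$treated$pre
#> <perfusion_fit> RBV A = 9.996 a.u., RR beta = 0.03998 1/s, y0 = 0.5035 (n = 598, R2 = 0.9998)
cmp$fits$treated$post
#> <perfusion_fit> RBV A = 9.998 a.u., RR beta = 0.02 1/s, y0 = 0.502 (n = 178, R2 = 0.9999)
```

The flashes are auto-detected at the protocol times (300 s, 630 s); the
fitted treated-ROI rate drops from 0.040 to 0.020 s⁻¹ while the plateau (RBV)
is unchanged, so the control-normalized ΔRR reads −50% — the simulated ground
truth. Volumetrics on a swept phantom:

```r
sw <- simulate_sweep("sphere", radius = 5, step = 0.2, pixel_spacing = 0.1,
                     contrast_fraction = 0.1, seed = 2)
tumor_volume(sw$sweep)        # 524 mm^3  (4/3*pi*5^3 = 523.6)
normalized_rbv(sw$sweep)      # 250.0 a.u./mm^3
```

A thin CLI wraps the same functions
(`exec/sonoperf simulate|extract|fit|volume|compare ...`); the methods
vignette (`vignettes/qceus-perfusion-monitoring.Rmd`) documents the model,
defaults and numerical choices.

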