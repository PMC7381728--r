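---
title: "Destruction–replenishment qCEUS analysis for sonopermeation monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Destruction–replenishment qCEUS analysis for sonopermeation monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoperf)
```

## The measurement problem

Sonopermeation — ultrasound-driven microbubble oscillation that transiently
increases vascular permeability — is only useful if its effect on the tumor
vasculature can be monitored non-invasively while therapy is delivered.
Quantitative contrast-enhanced ultrasound (qCEUS) provides that readout.
Microbubble contrast agents are strictly intravascular blood-pool tracers;
during a constant-rate infusion their steady-state concentration in an imaging
plane reflects local blood volume, and the *rate* at which they refill the
plane after being destroyed reflects local blood flow velocity.

The classic destruction–replenishment experiment therefore runs: infuse
microbubbles to steady state, apply a high-MI flash-destruction pulse to clear
the imaging plane, and watch the contrast signal replenish. The mean linear
intensity of a region of interest (ROI) follows

$$y(t') = y_0 + A\,\bigl(1 - e^{-\beta t'}\bigr),$$

where $t'$ is time since reflow began, $A$ (the plateau above the baseline
$y_0$) is the **relative blood volume** (RBV, arbitrary linear units) and
$\beta$ is the **reperfusion rate** (RR, s⁻¹), proportional to blood flow
velocity. In a monitoring run two flash pulses bracket the therapy — one
before treatment cycles begin and one after — so each ROI yields a *pre* and a
*post* replenishment fit, and the treated ROI can be compared against an
untreated control ROI to cancel systemic drift.

This package implements that entire chain — TIC extraction, flash detection,
segment fitting, volumetrics, paired inference — together with a synthetic
phantom generator with exact ground truth, so every stage is testable without
animal data.

## The monitoring protocol emulated by the generator

The default scenario (`default_scenario()`) emulates a two-flash monitoring
run on a constant-rate infusion:

| parameter | default | units | meaning |
|---|---|---|---|
| `time_to_steady` | 300 | s | infusion wash-in reaches ~99% of plateau |
| `flash_times` | 300, 630 | s | initial (pre) and final (post) destruction pulses |
| `recirculation_delay` | 30 | s | dead-time before fresh bubbles re-enter the plane |
| treated `A`, `beta` | 10 a.u., 0.04 s⁻¹ | — | focal-zone kinetics |
| control `A`, `beta` | 8 a.u., 0.05 s⁻¹ | — | reference-region kinetics |
| `beta_multiplier` | 1 | — | treatment effect on treated-ROI β after flash 1 |
| noise | Rayleigh, scale 0.1 | — | ~5% relative sd speckle |
| grid | 64 × 64 px, 2 Hz, 750 s | — | acquisition geometry |

Reperfusion rates of 0.03–0.05 s⁻¹ are typical of poorly perfused experimental
tumors, and the 300 s / 630 s flash timing with a 30 s recirculation gap
mirrors a standard 10–12 min monitoring infusion. The recording extends ~120 s
past the final flash so the post segment spans at least one characteristic
time $1/\beta$ even when therapy halves the rate; shorter recordings make the
post-fit plateau poorly identified.

Wash-in before the first flash is modelled as a saturating exponential with
rate $\ln(100)/t_\mathrm{steady}$, which keeps the pre-flash plateau
well-defined without simulating infusion-pump physics. The flash itself is an
instantaneous reset to $y_0$: real destruction pulses last a few seconds, but
that dead-time is absorbed into the recirculation delay, during which the
simulated signal stays at baseline. The treatment effect multiplies the
treated region's β for replenishment segments *after* the first flash, so the
pre segment carries the untreated rate and the post segment the treated one —
exactly the contrast the paired analysis is designed to detect.

### Noise families

CEUS magnitude images are speckle-dominated, so the default noise model is
multiplicative Rayleigh speckle, blended to be mean-preserving: each sample is
multiplied by $(1-s) + s\,Z$ with $Z$ a mean-one Rayleigh draw and $s$ the
scale (relative sd $\approx 0.52\,s$; the default $s = 0.1$ gives ~5%).
Additive and multiplicative Gaussian models are provided for unit tests and
calibration studies. None of these families is calibrated to any particular
scanner — the published protocols do not state the instrument's noise
statistics — so they are stand-ins that bound realistic behavior rather than
reproductions of it. Image-level simulation draws noise independently per
pixel per frame; TIC-level simulation (`simulate_tic()`, cohort
`level = "tic"`) draws once per frame on the ROI mean, which is the correct
marginal for ROI-level analysis and orders of magnitude faster for
Monte-Carlo work.

What the generator deliberately does **not** emulate: bubble acoustics,
attenuation and beam profiles, motion, intra-region kinetic heterogeneity
(regions are piecewise-constant), and therapy-cycle transients between the two
flashes. Passing tests therefore demonstrate correctness of the analysis
chain under idealized speckle-corrupted kinetics, not robustness to motion or
scanner artifacts.

## Numerical choices in the analysis chain

**Linearization.** Quantification must run on linear echo-power data, never on
log-compressed video. `linearize()` applies amplitude (20·log₁₀)
decompression, $v_\mathrm{lin} = 10^{(v/v_\mathrm{max} - 1)\,DR/20}$, mapping
the maximum code to 1.0 and code 0 to the dynamic-range floor. Amplitude
rather than power decompression is a convention choice — scanner mappings are
rarely published — and the parameters used are recorded in the sequence
metadata so results remain auditable. `extract_tic()` refuses log-compressed
input outright. Compressed codes are kept continuous: quantizing to integer
codes at an 8-bit depth would already cost ~1% round-trip error at 60 dB,
swamping the quantities being measured.

**Flash detection.** A frame is an event candidate when its intensity falls
at or below $(1-f)$ times the median of the preceding `window` frames
(defaults $f = 0.5$, window 5); candidates within a 5 s refractory period
merge to the first. The ratio form makes detection exactly invariant to
global intensity scaling, and the trailing *median* makes it robust to
speckle spikes.

**Segmentation.** Segments are anchored at each flash but re-zeroed at
`flash_time + recirc_delay`, with samples during the dead-time excluded.
Re-zeroing at the flash instead would fold the delay into the fit and bias
$\hat A$ by $e^{\beta\,\delta}$ (~3× at β = 0.04 s⁻¹, δ = 30 s); anchoring the
model at reflow onset keeps both parameters unbiased. Both the flash time and
the fit origin are recorded on every segment. Segments shorter than 8 samples
are dropped with a warning — below that, a three-parameter exponential fit is
not meaningfully constrained. Only the first and last detected flashes are
fitted in the monitoring analysis; transients from therapy cycles between
them never enter a fit window.

**Fitting.** `fit_replenishment()` runs bounded Levenberg–Marquardt least
squares with an analytic Jacobian (cost/parameter tolerances 10⁻¹², ≤ 500
iterations), bounds $A \ge 0$, $\beta \in (10^{-6}, 10]$ s⁻¹, $y_0 \ge 0$.
Initialization is deterministic and data-driven: the plateau is the mean of
the last 20% of samples, $\hat A_0$ the plateau minus the floor, and
$\hat\beta_0 = 1/t_{63}$ from the first crossing of 63.2% of the rise (0.01
s⁻¹ when the curve never gets there). The textbook model has no baseline
term, but real TICs have a nonzero floor, so $y_0$ is fitted by default and
reported; `fit_offset = FALSE` restores the strict two-parameter form.
Constant segments are reported `converged = FALSE` with reason
"unidentifiable beta" rather than producing an arbitrary rate. Confidence
intervals use the local curvature (Gauss–Newton) approximation.

**Derived metrics.** The AUC over $[0, T]$ is computed analytically,
$y_0 T + A\,(T - (1 - e^{-\beta T})/\beta)$, folding RBV and RR into one
number; the perfusion index is the classic flow proxy $A\beta$. Neither has a
published reference value in the motivating protocols; they are provided as
metrics, not endpoints.

**Volumetrics.** Stepped sweeps use a slab model: each slice represents a
slab of thickness equal to the step, so
$TV = \sum \text{mask area} \times \text{step}$ with no inter-slice
interpolation — at 0.2 mm stepping the discretization error on a 5 mm-radius
sphere is below 0.1%. Contrast-derived blood volume is the sum of
supra-threshold linear contrast inside the tumor mask (threshold default 0,
recorded in the output; a pixel-count variant is available), and
`normalized_rbv()` divides by TV. Phantom cross-sections use pixel-center
(midpoint) inclusion, which makes axis-aligned box volumes exact on aligned
grids. Tumor masks are inputs, drawn or simulated — B-mode segmentation is
out of scope.

**Paired inference.** Percent changes use the pre-phase parameter as base.
Control normalization defaults to the difference of percent changes
($\Delta_\mathrm{norm} = \Delta_\mathrm{treated} - \Delta_\mathrm{control}$),
which cancels additive systemic drift; a ratio mode
($100\,[(\beta_\mathrm{post}/\beta_\mathrm{pre})_\mathrm{treated} /
(\beta_\mathrm{post}/\beta_\mathrm{pre})_\mathrm{control} - 1]$) is provided
and the mode is stamped into every output. Cohort tests report both the
paired Student's t and the Wilcoxon signed-rank (exact distribution for
n ≤ 25 without ties or zeros, normal approximation otherwise; zero
differences dropped per convention); the primary p-value defaults to Wilcoxon
below n = 8 and t above, since the t-test's normality assumption is hard to
defend at very small n while the exact signed-rank test is then still
reasonably powered.

## A worked monitoring run

```{r example}
cfg <- default_scenario(beta_multiplier = 0.5, noise_scale = 0.1, seed = 9)
sim <- simulate_sequence(cfg)
cmp <- run_monitoring_pipeline(sim$sequence, sim$masks)
cmp
```

The treated ROI's reperfusion rate halves between the two flashes while its
blood volume is unchanged — the signature of a flow-rate effect without a
volume effect — and the control ROI is flat, so the control-normalized ΔRR
lands at −50%.

```{r cohort}
coh <- simulate_cohort(8, default_scenario(noise_scale = 0.1),
                       effect = 0.5, seed = 3, level = "tic")
cohort_statistics(lapply(coh, analyze_subject), metric = "rr")
```

## Validation scale

The shipped tests validate the chain at the following problem sizes, chosen
to exercise every code path at meaningful statistical resolution: noiseless
fits to 10⁻⁶ relative; 200 seeded segments at 5% relative noise checked
against a 400 × 400 brute-force SSE grid; flash detection over 20 noise
seeds; sphere/box sweep phantoms at 0.2 mm stepping; image-level cohorts of
n = 8 at β multipliers 0.25/0.5/2.0; and 1000 TIC-level null cohorts for the
paired test's empirical type-I error.

## Known limitations

- No motion correction or ROI tracking across frames; real cine loops need
  registration upstream.
- DICOM cine reading is not implemented; the supported interchange format is
  multi-page TIFF with a JSON sidecar (see `read_sequence()`).
- Linearization parameters (dynamic range, code mapping) must be supplied by
  the user for real scanner data; they are rarely published.
- ROI-level analysis only — no per-pixel parametric maps.
- The simulator's noise families are plausible stand-ins, not calibrated to
  any instrument, and regions are kinetically homogeneous.
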