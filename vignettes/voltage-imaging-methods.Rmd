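---
title: "Methods: models, parameters, and design choices in voltimg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in voltimg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltimg)
```

# Scope

voltimg analyses fluorescence recordings from genetically encoded voltage
indicators (GEVIs): fast, typically negative-going fluorescent reporters of
membrane potential. The package covers four experimental settings and the
synthetic data that emulates them:

1. **High-throughput screening** of indicator variants in multi-well plates
   under electric field stimulation (EFS).
2. **Voltage-clamp kinetics** of step responses recorded at high rate with a
   photomultiplier.
3. **Spike detection and scoring** of fluorescence during high-frequency
   firing, against command-voltage ground truth.
4. **Widefield in vivo imaging** with a dual-camera green/red system, where
   heartbeat and slower hemodynamic fluctuations contaminate the voltage
   signal and are removed by reference-channel regression, followed by
   spectral analyses (PSD, coherence with LFP, stimulation-frequency power
   maps).

# The exponential-with-onset kinetics model

The fluorescence response to a command-voltage step is modelled as a constant
baseline up to an onset time $t_0$, then a mono- or bi-exponential relaxation
toward a plateau $c$:

$$F(t) = c + \big(k\,e^{(t-t_0)\lambda} + k_2\,e^{(t-t_0)\lambda_2}\big)\,[t>t_0]
       + (k + k_2)\,[t \le t_0],$$

with $\lambda, \lambda_2 < 0$ and time constants $\tau_i = -1/\lambda_i$. The
onset $t_0$ is a fitted coefficient, not an input: shutter timing and filter
delays make the true transition time uncertain at the sub-millisecond scale
that matters for a $\tau$ of half a millisecond.

`fit_exp_onset()` exploits the model's structure: for fixed $(t_0, \lambda,
\lambda_2)$ the remaining coefficients are linear, so every objective
evaluation solves the linear subproblem exactly (variable projection) and only
the onset and rates are searched numerically (Nelder–Mead). Because the
indicator function makes the objective only piecewise-smooth in $t_0$, the
search is multi-started on a grid of onsets (default 11 points across ±10 ms)
crossed with log-spaced initial rates; starts are first screened cheaply on a
decimated copy of the data and the few best are polished on the full data. The
best fit by residual sum of squares wins. On noiseless model data this
recovers all coefficients to better than $10^{-6}$ relative error; the fit is
flagged *degenerate* (no $\tau$ reported) when the total fitted amplitude is
below 3× the baseline noise sd.

Two reporting conventions are deliberate design choices, flagged in the
output:

* **Fraction fast** is $100\,|k_\mathrm{fast}|/(|k_\mathrm{fast}| +
  |k_\mathrm{slow}|)$ — the amplitude-ratio convention, chosen because the
  resulting percentages of the two components sum to 100 and match how
  bi-exponential fits are usually summarised.
* **Model order selection** (`select_model()`) uses the small-sample-corrected
  AIC plus an amplitude floor: order 2 is returned only when it improves AICc
  *and* both components exceed 3× the baseline noise sd. A second component at
  the noise floor is parsimony-rejected.

Depolarization and repolarization transitions are fitted independently, each
on a window from 0.1 s before to 1 s after its nominal onset, after divisive
photobleaching correction from the held-voltage baseline segments
(`correct_baseline_bleach()`) and block-mean decimation to 20 kHz
(`downsample()`).

# Screening analytics

Screening movies are processed in a fixed chain (`screen_fov()`):

* **Background and initial mask.** The background is the dominant
  low-intensity mode of a 256-bin histogram over the lower half of the
  intensity range — robust to bright foreground. The initial mask keeps
  pixels above background + 5× a MAD-based robust background sd; the exact
  thresholds used on real rigs are rig-specific, so the multiplier is a
  documented, configurable default. Saturated pixels are excluded outright.
* **Trend removal.** A three-term exponential (plus offset) is fitted to the
  mask-summed trace with stimulation windows excluded; the fitted *rates* are
  shared and per-pixel amplitudes are re-estimated by linear least squares;
  each pixel is divided by its own trend. Divisive (not subtractive) removal
  matches the multiplicative way photobleaching scales fluorescence.
* **Responsive-pixel selection.** Pixels are ranked by Pearson correlation of
  their detrended trace with the overall trace and accumulated in batches of
  200; the prefix of batches whose summed-trace SNR is maximal becomes the
  secondary mask. SNR is defined here (the field leaves it open) as the peak
  absolute deviation across stimulus events divided by the sd of the
  event-free baseline of the summed trace; baseline excludes 0.5 s after each
  event so that response recovery tails do not leak into the noise estimate.
  Ties are broken toward fewer batches (smaller masks). The whole-mask
  correlation uses all samples, stimulation included.
* **Response amplitude** is the signed peak fractional deviation from a local
  pre-event baseline; widths are measured at a configurable fraction of peak
  (default 30%). This indicator family is negative-going, so amplitudes are
  stored signed and typically negative.

Brightness is the green/red mean ratio over the secondary mask,
pixel-count-weighted across fields of view. Photostability reports the photon
budget (area under the normalized trace, with the last frame held to the end
of its exposure so a constant unit trace of duration $T$ yields exactly $T$)
and the half-life (first crossing of 0.5 by a three-term exponential fit,
absent if never reached). Spectral scans are blank-subtracted,
peak-normalized, excluded when more than ±10% efficiency remains at the grid
ends (a sign of failed autofluorescence correction), then averaged.

# Spike detection and scoring

Ground-truth spikes come from the command voltage via local maxima with
prominence ≥ 10 mV and separation ≥ 1 ms. Fluorescence spikes use the simple
threshold method: rectify by polarity, high-pass at 60 Hz (removing baseline
rise during current injection), estimate σ from a spike-free 500-ms baseline,
and keep peaks exceeding 2σ above the baseline level. The high-pass is a
zero-phase 4th-order Butterworth (the filter family is a documented choice;
only the cutoff is inherited from the protocol).

Scoring walks the ground truth first-to-last; each truth spike takes the
nearest unmatched detection within ± one time bin (ties to the earlier
detection) and the pair is removed. The automatic bin is the minimum
inter-spike interval of the truth train. TP/FP/FN, precision, recall and
$F_1 = 2PR/(P+R)$ follow. Degenerate conventions are fixed and tested: an
empty side gives precision/recall/F1 of 0, except that empty truth *and*
empty detections score F1 = 1 (perfect silence). For spacing ≥ 2 bins the
greedy pass provably attains the maximum matching; the tests verify this
against brute force on up to 12 spikes. Scoring of high-frequency episodes is
restricted to a half-open stimulation window `[0.25, 0.75)` s.

# The widefield artifact-removal pipeline

Stages, in order (`run_pipeline()`): per-channel background subtraction →
divisive two-term bleach-template detrend of the green channel (template from
0.5-Hz-lowpassed trial traces, averaged, then fitted) → ΔF/F₀ on both
channels with a 2–2.5-s baseline window → 70-Hz lowpass on the green channel
→ one ordinary-least-squares regression step per configured reference band,
high to low. Each step scales the band-filtered red ΔF/F₀ to the green trace
and subtracts it, leaving a residual orthogonal to the regressor; steps are
idempotent projections and never increase variance. Default bands are
10–30 / 1–10 / 0–1 Hz (awake; heartbeat near 10–14 Hz) and 4–20 / 1–4 /
0–1 Hz (anesthetized; heartbeat near 5 Hz); a five-band set for simultaneous
LFP sessions is available through a custom configuration. Analyses run per
2×2-pixel ROI by default; `roi_size = 1` gives the pixel-wise path.

Deliberate choices: filters are zero-phase 4th-order Butterworth with
half-power band edges (a documented dialect; since the identically filtered
regressor is used consistently on both channels, the regression is
insensitive to the exact filter family); regression is scale-only ("scaled
and subtracted"), with an optional intercept for the DC band; bleach removal
is divisive by default with a subtractive flag; ΔF/F₀ is not recomputed after
regression.

# Synthetic data: what it emulates, and what it does not

The dual-channel generator composes, per pixel,

$$G = B + \mathrm{bleach}(t)\,G_0\,(1 + v + a_g + n_s) + \varepsilon_g,\qquad
  R = B + R_0\,(1 + \gamma\,a_r + n_s) + \varepsilon_r,$$

with heartbeat and slow hemodynamics $a$ shared between channels (per-channel
gain $\gamma$), shared illumination noise $n_s$ added identically to both
channels before independent sensor noise $\varepsilon$ (the single-light-source
design is what makes reference regression work), and the voltage $v$ present
only in the green channel. The heartbeat is an amplitude-modulated sinusoid
with a slow ±5% random-walk frequency jitter: a narrowband artifact inside
the regression bands, not a trivially removable pure tone. Bleaching is
multiplicative on the green channel, mirroring the divisive correction.

Artifact fractions are not published for real rigs, so the defaults are fixed
study conditions chosen once at realistic magnitudes and documented here:
heartbeat 5% ΔF/F (red gain 1.3), slow hemodynamics 2% in 0.1–1 Hz, shared
illumination noise 0.5%, sensor noise 1%, and a broadband 0.5–10 Hz voltage
signal at 2% — a cortical-signal-like band deliberately overlapping the
artifact bands. Default trials are 20 s at 200 Hz on a 16×16-pixel frame
(the spatial dimension carries no structure beyond independent sensor noise,
so a small frame loses nothing statistically); heartbeat 5 Hz anesthetized,
12 Hz awake. Sensor noise is Gaussian by default — regression math is
noise-model agnostic — and the generator seeds all randomness, so identical
(config, seed) pairs are bit-identical.

What passing tests on these data do **not** show about real recordings: no
optical point-spread function, no vascular geometry, no motion, no Poisson
photon statistics by default, and no nonlinear indicator response. The
pipeline property they do establish is the linear-algebraic one: shared
narrowband artifacts are removed to the reference-noise floor while
out-of-artifact-band signal is preserved.

Two measurement subtleties are worth recording. First, the before/after PSD
ratio *at the heartbeat bin* saturates at the clean-signal floor: with a
broadband voltage signal overlapping 5 Hz, a perfectly corrected trace still
holds genuine voltage power there (the corrected power equals the
ground-truth voltage PSD at that bin). Artifact suppression is therefore
quantified on the ground-truth heartbeat component — the projection of the
trace onto the known heartbeat before vs after correction — which the
pipeline attenuates by ≥ 20 dB (typically 35–45 dB). Second, single-trial OLS
necessarily removes the part of the voltage that is *in-sample* correlated
with the band-limited reference; at 20 s per trial the chance correlation
between two band-limited processes sharing a narrow band is non-negligible,
so retention is assessed on the clean signal filtered away from the artifact
bands (1.2–3.5 Hz and 6–10 Hz), where it exceeds 95%.

# Spectral analyses

`welch_psd()`, `spectrogram()` and `coherence()` are Hann-windowed,
mean-detrended, one-sided density estimates built directly on the FFT (no
installed R package provides Welch averaging with cross-spectra); the PSD
satisfies Parseval to within a few percent and was validated against an
independent implementation. Spectrogram defaults — 0.5-s segments, 75%
overlap — and the 2-s coherence segments are configurable and echoed in
outputs, since the upstream processing conventions leave them open. Power at
a target frequency is the single nearest spectrogram bin, the simplest
faithful reading. LFP conditioning follows the stated order: invert →
block-mean downsample to the imaging rate → 70-Hz lowpass → optional 60-Hz
notch (skipped when tagging 60-Hz stimulation). Shuffled controls are seeded
derangements (no trial ever pairs with itself), 1000 by default.

# Numerical choices and degenerate inputs

* Exponential trend fits constrain rates negative, include a constant offset,
  and multi-start from 8 log-spaced rate sets; the family is intrinsically
  ill-conditioned, so the best-RSS fit is reported and non-convergence is
  flagged rather than silently returned. Constant traces short-circuit to a
  flat trend.
* Divisive detrending refuses non-positive trends; per-pixel detrending is
  restricted to mask pixels (background pixels have no positive trend to
  divide by) and drops collinear columns when two fitted rates coincide.
* All time indexing is 0-based, time-major, in seconds; frame $i$ sits at
  $i/\mathrm{rate}$. Rate metadata is mandatory on load and never guessed.
* Zero-phase filtering reflect-pads the record to suppress filtfilt edge
  transients; tests that compare detections or flatness avoid the outermost
  few tens of milliseconds where a residual transient can survive.
* Empty masks warn rather than fail (a dim well is a result, not a crash);
  an all-saturated frame is an error.

# Problem sizes

The shipped tests and the acceptance script use 50 replicates for the
kinetics recovery experiments (20-kHz traces, 22 001 samples each), three
seeded 20-s synthetic recordings for the pipeline property, and 24×24 to
32×32-pixel fields of view for the screening oracle comparisons. These sizes
were chosen so the full suite exercises every code path at full fidelity
while remaining comfortable to run on a laptop; the statistical conclusions
are insensitive to scaling them up.
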