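---
title: "Phase-binned signal detection: models, pipeline and design choices"
author: "alphaSDT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-binned signal detection: models, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaSDT)
```

## The scientific question

Posterior alpha-band (7–14 Hz) EEG oscillations are thought to impose
rhythmic excitability cycles on visual cortex, so that the phase of the
ongoing oscillation at stimulus onset should modulate what an observer
perceives. Hit-rate modulations alone cannot distinguish *how*: a phase
effect on the decision criterion, an additive or multiplicative gain on
the internal evidence, and a phase-dependent change of internal noise all
move hit rates. The analyses in this package separate these accounts with
signal detection theory computed *within phase bins*, double-pass response
consistency, and reverse-correlation estimates of sensory tuning.

## Observer models

All observers share an equal-variance evidence axis. On each trial the
evidence X is compared with a fixed threshold λ; "yes" is reported when
X > λ. Confidence is 1 plus the number of cutpoints below |X − λ| (three
increasing cutpoints, so a 1–4 scale; confidence is generated only for
schema completeness).

* **Variance reduction** — X ~ N(µ, σ(φ)²) with µ = µ_n for noise trials
  and µ_n + d'_base·σ₀ for targets, and

      σ(φ) = σ₀ (1 + m cos(φ − φ_opt − 180°)),

  minimal (σ₀(1 − m)) at the optimal phase φ_opt. Hit rate is maximal and
  false-alarm rate *minimal* at φ_opt (counterphase HR/FAR) whenever
  µ_n < λ < µ_s — the defining signature of noise reduction.
* **Multiplicative gain** — X ~ N(g(φ)µ, (g(φ)σ₀)²) with
  g(φ) = 1 + m cos(φ − φ_opt) and fixed λ. Both HR and FAR are maximal at
  φ_opt. This only works if the noise distribution has a nonzero mean to
  scale, which is why the noise mean defaults to µ_n = 1 rather than 0: a
  pure gain applied to a zero-mean noise distribution would leave the
  false-alarm rate untouched and the two models would be indistinguishable
  on FAR.
* **Template observer** — evidence is a Gaussian-weighted readout of the
  trial's stimulus energy profile (spatial frequency × orientation), with
  tuning widths that broaden from `templateSd` at φ_opt to
  `templateSd × templateSdMod` at the worst phase, plus internal noise
  N(0, σ(φ)). This is the generative counterpart of the
  reverse-correlation analysis: broader tuning at the suboptimal phase is
  what a larger fitted SD modulation factor should recover.

Single-harmonic cosine modulations are used throughout: they are the
simplest parameterisation consistent with a phasic effect analysed in
eight bins, and any smooth unimodal modulation projects mainly onto this
first harmonic.

`observerRates()` returns the closed-form HR(φ)/FAR(φ) curves of the two
Gaussian observers; the Monte-Carlo simulators converge to these at the
usual 1/√n rate, which the tests exploit as an oracle.

## The synthetic session and stimuli

`makeSessionDesign()` reproduces the reference session layout: 43 blocks
of 140 trials, 70 unique stimuli per block, each presented twice in
identical order (trials 1–35 repeated on 36–70, and 71–105 on 106–140),
50% target prevalence per block, sides uniform. Both passes share the
target flag, side and the stimulus RNG key, so re-rendering yields
pixel-identical images — the invariant the double-pass analysis relies
on. For very small blocks the run length shrinks to the number of unique
stimuli (a 4-trial block with 2 unique stimuli runs s1, s2, s1, s2).

Noise patches are constructed in the Fourier domain with unit amplitude
inside 0.25–4 cpd and zero outside (random phases), apertured to a 3°
disc, and rescaled to 70% RMS contrast over the aperture. Targets are
vertical 2-cpd gratings with random spatial phase, scaled to the titrated
RMS contrast (default 15%). The raster defaults to 48 px/°, the value
implied by the reference display geometry (74 cm viewing distance,
53.4 cm / 1920 px screen), and is configurable; the raster-intensive
tests use 16 px/°, which is still four times the Nyquist limit for the
4 cpd band edge. The target's envelope is the aperture itself by default
(an explicit Gaussian envelope SD is configurable, since tuning the
envelope is not the point of the analyses).

Synthetic EEG (`simulateAlphaEEG`) is a cosine at the individual alpha
frequency whose phase at stimulus onset is uniform per trial, projected
through signed channel weights — posterior channels positive, AFz negative
— plus independent 1/f noise. The signed two-pole topography is the
minimal configuration that reproduces the frontal–occipital phase
opposition; no realistic forward model is attempted. Phase uses the cosine
convention (0° at the oscillation peak) and degrees everywhere.
`propagatePhase()` exposes the generative fact that the noise-free phase
advances linearly at the oscillation frequency; it serves as the analytic
stand-in for the filter–Hilbert chain wherever EEG synthesis itself is not
under test.

### What the generator does not emulate

No stimulus-evoked responses, eye or muscle artifacts (rejection is tested
by injecting threshold-crossing spikes), alpha amplitude fluctuations,
non-stationary IAF, or volume-conduction mixing beyond the two-pole
weights. Passing tests therefore demonstrate that the pipeline recovers
known ground truth under clean assumptions — not that recorded EEG meets
those assumptions.

## The phase-estimation chain

1. **Preprocessing** (`preprocessEpochs`): 0.1 Hz high-pass, resampling to
   500 Hz, rejection of trials exceeding ±150 µV between −0.8 and +0.2 s,
   average re-referencing. A median-reference first pass is available but
   off by default for synthetic data, which has no gross artifacts.
2. **IAF** (`estimateIAF`): Hamming-tapered −500–0 ms windows, zero-padded
   ×5 (0.4 Hz resolution), power spectra averaged over six parieto-
   occipital channels and all trials, peak within 7–14 Hz. The peak must
   be a local maximum strictly inside the band *and* exceed 1.2× the
   median band power: a flat spectrum always contains interior ripples, so
   a local-maximum test alone cannot operationalise "no discernable alpha
   peak"; the prominence factor does. Power (squared magnitude) is used —
   for a single peak the location is the same as for amplitude spectra.
3. **Taper** (`applyPoststimTaper`): gain 1 up to +30 ms, linear to 0 at
   +70 ms, exactly 0 after — evoked activity cannot leak backwards through
   the non-causal filter.
4. **Filter–Hilbert** (`bandpassPhase`): Hamming-window sinc FIR band-pass
   at IAF ± 2 Hz, applied as a centred symmetric kernel (zero-phase by
   construction; group delay below one sample). The kernel length follows
   the 3.3/(transition bandwidth/fs) Hamming rule. The transition
   bandwidth defaults to 1 Hz (1651 taps at 500 Hz): with a 2 Hz
   transition the taper's asymmetric truncation of the post-stimulus
   signal leaves a systematic ≈3° phase bias at onset, while the longer
   kernel keeps the noise-free onset error below 1° RMS. Epochs must be at
   least one kernel long; the analysis window (−700–0 ms) sits more than a
   half-kernel away from both epoch edges, outside the edge-artifact span.
   The analytic signal is computed at 500 Hz and *then* interpolated (as a
   complex signal) onto the 150 Hz grid before taking angles — decimating
   after phase extraction would wrap; interpolating the narrowband
   analytic signal preserves phase. "Phase at time t" means the sample
   nearest t on the 150 Hz grid.
5. **Binning** (`binPhase`): eight bins centred at 0°, 45°, …, 315°,
   half-width 22.5°, lower-inclusive boundaries (22.5° falls in the 45°
   bin).
6. **Channel selection** (`selectAlphaChannels`): prestimulus band power
   in IAF ± 2 Hz over 17 posterior channels, top three, ties broken by
   candidate-list order so selection is deterministic.

## Coupling statistics

For each time point and channel, trials are split by phase bin; per-bin
hit/false-alarm counts get the loglinear correction (+0.5 / +1 — the
standard constants for that correction) and the chosen metric (d',
criterion, HR or FAR). The eight values are summed as vectors at their bin
centres. The *sum* convention is the default: for a profile
a + A·cos(θ_b − φ) it returns exactly ρ = 4A, θ = φ, and a constant
profile cancels to 0. A mean mode (÷8) is available since both
conventions appear in the literature; the choice rescales ρ but changes no
inference.

Per-channel ρ series are averaged across the selected channels, then
smoothed with a 50 ms centred moving mean (7 samples at 150 Hz, shrinking
at the edges). Permutations shuffle the behaviour labels jointly against
the trials' phase time courses and re-run the identical chain — binning,
metric, resultant, channel average, smoothing — yielding per-time-point
95th-percentile thresholds. Supra-threshold runs of adjacent samples form
clusters; the null is the *maximum* cluster size per permutation
(max-statistic FWER control — the natural reading of cluster correction
when the alternative, pooling all null clusters, would not control
family-wise error), and a cluster's p is the fraction of permutations
whose maximum reaches its size. Subject-level significance compares the
−450–0 ms time-average of the real ρ against the 95th percentile of the
time-averaged permuted ρ; `binomialReplication` then gives the upper-tail
probability of the observed number of significant subjects at α = 0.05.

With ~200 permutations the realised false-positive rate of "any
significant cluster" fluctuates a few points around the nominal 5% —
the discreteness of the fraction-type p estimator and the finite-sample
thresholds both contribute — which is why the calibration check allows
7.5% over 200 replicate simulations.

`alignToBestBin` circularly shifts each subject's binned metrics so the
highest d' lands in bin 8 (ties to the lowest index), applies the same
shift to criterion/HR/FAR, and drops bin 8: purely for visualisation,
never for inference, since aligning to the maximum biases it upward.

The resultant angle estimates the optimal phase *at each time point*; it
advances with the oscillation, so quantities defined "at onset" must
either be read at t = 0 or back-rotated by 360°·IAF·t before circular
averaging.

## Double-pass consistency

`findPairs` keeps stimulus pairs whose two presentations both survived
rejection. For every time point (−450–0 ms) and selected channel, a trial
is in the good phase if its phase lies strictly within 90° of that cell's
resultant angle (the 90° boundary counts as bad); a pair is "both optimal"
when both members are good, and "otherwise" pools pairs with one *or* two
bad members. The proportion of response-consistent pairs (same yes/no —
confidence is not consulted) is computed per cell and condition and
averaged, unweighted, over cells; cells with an empty condition are
excluded with a warning (the pair counts per cell are unequal, and no
principled weights exist, so unweighted means keep the estimator simple).
A two-tailed paired t-test compares conditions across subjects. Under
variance reduction the optimal phase has a smaller σ, so both yes-rates
sit further from ½ and identical stimuli elicit the same response more
often — consistency rises with no change in the stimulus.

## Reverse correlation

The filter bank holds quadrature Gabor pairs on 15 linear SF steps
(0.5–4 cpd) × 19 orientation steps (−80° to +80°), 285 cells. The
envelope is an isotropic Gaussian with SD 0.8 carrier cycles (≈1 octave);
kernels are unit-energy and the even kernel is DC-balanced. Energy is the
quadrature modulus E = √((S·g_sin)² + (S·g_cos)²) of centred inner
products — the printed formula, not a full convolution, which is
appropriate for an aperture-limited patch. Energies are z-scored per cell
separately within target-present and target-absent trials (before any
phase split, matching the order of operations of the procedure it
implements), then each cell is regressed on the yes/no response with a
standard probit GLM p(yes) = Φ(β₀ + β₁E). Cells with (near-)perfect
separation have β₁ capped at ±10 with a warning rather than dropped. The
β₁ grid is folded across orientation sign (idempotent), giving 15 × 10
classification images.

Trials are split once into optimal/suboptimal sets: per channel, the phase
at t = 0 is compared (±90°) with the channel's time-averaged resultant
angle over −450–0 ms; a majority over the three channels decides, ties
going to suboptimal. A 2-D Gaussian
p₁·exp(−[(x−p₂)²/2p₃² + (y−p₄)²/2p₅²]) + p₆ is least-squares fitted to
the optimal-phase CI (Levenberg–Marquardt, multi-start: argmax centre
plus four jittered restarts, best residual wins); the suboptimal CI is
then refit with a free centre and three multiplicative modulation factors
(gain, one common SD factor, offset). When the reference offset is ~0 the
offset factor is undefined and an absolute offset is fitted and flagged
instead. Bootstrap inference resamples subjects with replacement
(basic percentile two-sided p-values against 1); the difference CI
subtracts optimal from suboptimal draws per cell with two-sided bootstrap
p-values and deliberately no multiple-comparison correction (flagged in
the output).

Note that the CI width convolves the observer's template with the bank's
own bandwidth, so a template-level broadening factor is attenuated in the
fitted SD ratio; quantitative recovery of an SD modulation factor is
therefore checked at the CI-grid level, while the stimulus→energy→probit
route is validated on centre recovery and calibration.

## Numerical choices and degenerate inputs

* Inverse-normal via `qnorm` (machine precision); no table lookups.
* Loglinear correction yields rates strictly inside (0,1); zero-trial
  classes give the uninformative 0.5.
* Resultant angles are undefined (NA) when ρ is numerically zero; the
  V-test returns V = 0, p = 0.5 for a vanishing resultant.
* Identical permutation seeds give byte-identical thresholds, clusters
  and reports; every pipeline stage derives a child seed from the master
  seed.
* Argmax ties (best bin, channel ranking) break toward the lowest index.
* A zero-variance consistency difference raises a degenerate-test error
  rather than returning NaN.

## Problem sizes

The test-suite and acceptance simulations use sizes chosen to make
Monte-Carlo error comfortably smaller than the effects under test: 50k
trials for rate-level oracles, 4000-trial observers for recovery checks,
200 replicate simulations × 200 permutations for null calibration, 500
bootstrap iterations for modulation recovery, and 16 px/° rasters for
image-domain checks. Full-scale runs (6020 trials, 1000 permutations,
10000 bootstraps, 48 px/°) use the same code paths via
`pipelineConfig("paper-scale")`.

## Known limitations

* The generative EEG has a fixed-amplitude oscillation; amplitude–phase
  interactions (e.g. power-dependent phase estimability) are not
  modelled.
* The multiplicative-gain observer's FAR signature depends on the
  convention µ_n = 1; other noise-mean conventions rescale the
  discriminability of the two models.
* `preprocessEpochs` implements threshold rejection only — no ICA or
  channel interpolation.
* The double-pass module estimates consistency contrasts only; it does
  not fit internal/external noise ratios from consistency–accuracy
  curves.
* File-based exchange is CSV/JSON only; epoched containers live in
  memory as S4 objects.
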