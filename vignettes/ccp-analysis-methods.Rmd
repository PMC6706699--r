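---
title: "Models and methods behind ccptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccptools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccptools)
```

`ccptools` quantifies clathrin-coated pit (CCP) biology from two kinds of
data: multi-channel TIRF microscopy (movies and fixed-cell stills) and
binding titrations (fluorescence anisotropy, SPR, ITC, NMR shift
perturbation). This vignette documents the models, the defaults, the
numerical choices, and what validation on synthetic data does and does not
establish.

## The imaging model and spot detection

A CCP is diffraction-limited, so its image in TIRF is modelled as an
isotropic 2D Gaussian on a locally constant background,

$$I(x, y) = A \exp\left(-\frac{(x-x_0)^2 + (y-y_0)^2}{2\sigma^2}\right) + c.$$

Candidates come from a difference-of-Gaussians band-pass (σ and 1.6σ,
matched to the PSF) followed by strict 8-neighbour local maxima above a
permissive threshold (3 MADs of the band-passed frame). The permissiveness
is deliberate: the statistical decision is taken by the fit, not the
candidate stage.

Each candidate is refined by damped Gauss–Newton least squares over a
square window (default half-width 4 px) with σ fixed to the configured PSF
width (1.1 px by default, appropriate for a 100×/1.49 NA objective with
6.45 µm camera pixels, i.e. 64.5 nm at the specimen; a free-σ refit is
available via `free_sigma`). Fixing σ stabilizes the amplitude test and is
standard for diffraction-limited detection.

**Amplitude significance.** The fitted amplitude is tested one-sided
against the residual background noise estimated at the location. The null
is $A = k\,\hat\sigma_{\mathrm{res}}$ with $k = \Phi^{-1}(1-\alpha)$, and
the statistic $(\hat A - k\hat\sigma_{\mathrm{res}})/\mathrm{se}(\hat A)$
is referred to a t distribution with (window pixels − free parameters)
degrees of freedom. Requiring the amplitude to exceed a noise *multiple* —
rather than merely to be nonzero — keeps the test honest under position
refinement: the fitted position adapts to local noise structure, which
would inflate a plain $A/\mathrm{se}(A)$ test well above its nominal level.
With the noise-multiple null, the measured false-positive rate on pure
noise stays at or below α (the suite checks ≤ α + 2% over 1000 Monte-Carlo
windows). On planted SNR-10 spots, recall and precision both exceed 0.95
and the localization error is below 0.15 px RMS.

**Master/slave measurement.** Slave channels are never detected
independently for paired statistics: each master detection fixes a
constrained fit in the slave channel, with the slave position bounded
within `slave_search_radius` (default 2 px; the search radius concept is
standard in dependent dual-channel detection, and the specific default is
our choice) of the master. The output is paired 1:1 and order-preserving,
including insignificant slave measurements, so downstream proportion
statistics see every master exactly once.

## Intensity normalization

Cell-to-cell expression differences are removed by distribution matching:
each cell's detection amplitudes are summarized as an empirical quantile
table on a fixed grid (99 percentiles); the reference is the across-cell
median at each grid point; and each cell receives the scale
$s = \sum_q Q_{\mathrm{ref}}(q) Q_{\mathrm{cell}}(q) / \sum_q
Q_{\mathrm{cell}}(q)^2$, the closed-form minimizer of the mean squared
error between the scaled cell distribution and the reference. The grid
formulation is our operationalization of "matching cumulative
distributions"; the closed form is verified against a brute-force grid
search in the tests. Channels are normalized independently by default (a
shared-factor variant can be had by passing the master's reference), since
the original choice is not documented in the sources this design follows.
Cells with fewer than 20 detections are refused rather than normalized
badly.

## Colocalization statistics

Pearson correlation captures only linear association of paired intensities,
so it is complemented by the proportion curve: master detections are sorted
by intensity (stable sort; ties keep input order and may straddle bins),
split into equal-count bins (default 10; any remainder goes to the
lowest-intensity bins so counts differ by at most one), and the per-bin
proportion of slave-significant detections is reported against the bin's
mean intensity. The significance flag is computed upstream with a single α
for all conditions being compared, which is what makes curves across
conditions directly comparable. Condition-level summaries use the Welch
(unequal-variance) form of the two-tailed unpaired t-test — the robust
default when only "two-tailed unpaired" is specified.

## Tracking and dynamic statistics

Linking is greedy mutual-nearest-neighbour between consecutive frames with
gap closing up to `max_gap` (default 2) missed frames and a displacement
cap (default 3 px). This is intentionally simpler than full LAP/Kalman
tracking: the synthetic scenes this package validates on enforce ≥4σ spot
spacing, where mutual-nearest-neighbour linking is essentially exact, and
crowded-scene tracking is out of scope.

Classification follows three rules, applied once per track:

* **persistent** — the track spans every frame of the acquisition (frames
  0 through n−1), regardless of amplitude. Persistent structures are
  excluded from lifetime analyses and reported separately as a density per
  µm².
* **bona fide** — the maximum master amplitude reaches the intensity
  threshold and the track lasts at least `min_frames` (default 4 frames,
  i.e. 8 s at the default 2 s interval).
* **transient** — everything else.

The "average lifetime of the 95th percentile" statistic is interpreted as
the mean of the lifetimes at or above the 95th percentile (the top 5% of
bona fide tracks); the percentile value itself is also reported
(`p95_s`) since the phrase admits both readings.

Slave positivity of a track requires ≥30% of its frames to carry a
significant slave detection. The 30% default is our choice (the
subcategorization criterion is not documented in the sources this design
follows); it is config-exposed, and the recovery tests show it reproduces
planted positive fractions of 0.65 and 0.31 within binomial confidence
intervals at n = 2000 when applied to bona fide tracks. Applying it to
short transients would inflate the rate (a 3-frame track passes with a
single false-positive frame), which is why positivity percentages are
computed over the bona fide population.

Cohort traces resample each track's intensity trace linearly onto a common
50-point axis spanning its own lifetime, then average pointwise (mean ±
SE; the SE of a single-track cohort is 0 by convention, and empty cohorts
yield no rows rather than errors). Cohort boundaries are configuration,
not constants.

**Recruitment timing.** Cohort-averaged traces are smoothed with a
Gaussian kernel of SD 1.2 samples (the documented analysis parameter for
2 s sampling) and the maximum is located with sub-sample precision by
cubic interpolation around the discrete argmax. The maximum recruitment
rate uses central differences of the smoothed trace, localized the same
way. Flat traces return the earliest maximum with a degeneracy flag; traces
whose smoothed maximum does not rise 3 robust noise SDs (from second
differences, which cancel linear trends) above the median are flagged
unreliable. Ties resolve to the earliest sample, which is also the
convention the triangle-trace tests pin down.

## Binding models

All fits use Levenberg–Marquardt nonlinear least squares (`minpack.lm`),
with dissociation constants log-parameterized to enforce positivity.
Standard errors for transformed parameters use the delta method.

* **Anisotropy**: $F = F_f + (F_b - F_f)\,[L]/(K_d + [L])$. A fit whose
  $K_d$ exceeds the largest ligand concentration is flagged
  `no_saturation` and reported unconverged.
* **SPR dissociation**: $R(t) = A_f e^{-k_f t} + A_s e^{-k_s t}$ with five
  deterministic multi-starts over log-spaced rate ratios; components are
  reported ordered $k_f > k_s$, and near-degenerate rate pairs are
  flagged. The default design covers a 510 s dissociation window.
  Association-phase kinetic modelling is deliberately out of scope.
  Amplitude-versus-concentration data are fit with the 1:1 isotherm
  $A(C) = A_{max} C/(K_D + C)$; a constant-offset term is off by default.
* **ITC**: independent single-site model with exact per-injection mass
  balance. The mixing convention is perfect mixing followed by overflow of
  the injected volume at post-mixing concentrations; bound complex comes
  from the quadratic solution of the 1:1 equilibrium, and the heat of
  injection i is $\Delta H \cdot V_0 (B_i - B_{i-1} V_0/(V_0+dV_i))$. The
  default design is 20 injections of 2.43 µl into a 170 µl cell (the
  low-volume cell consistent with a ~50 µl syringe schedule). Experiments
  with a Wiseman c-value outside [1, 1000] are flagged `low_information`.
  The implementation is verified against an independent numerical
  mass-balance oracle (free ligand solved by root finding) to 1e-6.
* **Shift perturbation**: $\Delta\delta = \sqrt{\Delta\delta(^1H)^2 +
  (\Delta\delta(^{15}N)/5)^2}$ applied exactly; residues assigned in only
  one state are dropped and reported, never treated as zero.

Concentrations keep the unit of their input axis ($K_D$ in µM data comes
back in µM); the ITC interface is molar.

## The synthetic-data generators

The generators define the study conditions for every validation:

* **Movies** default to the acquisition geometry of the live-cell data
  they emulate: 0.5 frames/s for 10 minutes (300 frames at 2 s), PSF σ
  1.1 px, 64.5 nm pixels. Spots are static Gaussians with pairwise spacing
  ≥ 4σ (scenes that cannot maintain this are refused with a crowding
  error — overlap handling is a non-goal). Noise is Poisson photon noise
  on the noiseless image plus Gaussian read noise, the standard sCMOS
  approximation; the sources specify no noise model, so defaults
  (background 100, read noise 4, amplitudes 100–150, hence SNR ≈ 10) were
  chosen once for test power, not biological fidelity. Lifetimes follow a
  two-population mixture — 40% transient (mean 6 s, low flat amplitude
  profile) and 60% bona fide (mean 40 s, piecewise-linear rise over the
  first 30% of the lifetime, plateau, fall over the last 20%, a shape
  consistent with published cohort profiles that have no documented
  generative form) — and persistent structures render at constant
  amplitude in every frame. The slave channel renders only
  Bernoulli-planted positive events at 0.8× the master amplitude.
* **Track tables** bypass image formation to test track statistics in
  isolation, with the same lifetime mixture and trace shapes and additive
  Gaussian noise.
* **Stills** place spots with the same spacing rule; secondary channels
  are populated at per-channel co-occurrence probabilities with amplitudes
  positively correlated to the master by a configurable coefficient.
* **Titrations** forward-simulate the three binding models with additive
  Gaussian noise.

Everything is deterministic given a seed (bit-identical reruns are
tested).

What passing these validations shows: the estimators are unbiased and
correctly calibrated *under the generative model* — well-separated static
spots, constant background, Gaussian/Poisson noise, step-free traces. What
it does not show: robustness to spot overlap, drift, photobleaching,
evanescent-field depth effects, or camera gain nonlinearity, none of which
the generators emulate. Conclusions about real data should be drawn with
those limits in mind.

## Numerical choices and degenerate inputs

* Gauss–Newton spot fits damp by step halving, clamp positions to the
  window (and slave positions to the search radius box), and cap
  iterations at 100 with a 1e-8 relative tolerance; non-convergent fits
  are flagged `valid = FALSE`, never silently dropped.
* Duplicate fits within 1 px merge keeping the higher amplitude.
* Equal-count binning distributes remainders to the lowest bins; every
  detection is counted exactly once.
* PCC on a zero-variance channel, normalization of all-zero intensities,
  lifetime statistics on < 20 tracks, and proportion curves on < 5·bins
  detections are explicit errors.
* Per-frame slave significance in track tables uses a one-sided z-test
  against a known or robustly estimated noise SD (median absolute
  successive difference / √2).

## Problem sizes used in validation

The shipped tests run deliberately scaled problems: recall/precision on 50
spots at 256², planted-fraction recovery at n = 800–2000 tracks and 1000
still spots, density-ratio recovery on 3 movie pairs at 96²×150 frames,
and 20–50 replicate fits per noise scenario. The acceptance script runs
the full-size versions (2000 tracks, 1500-spot stills, ten 128²×300-frame
movies per condition). These sizes give binomial/Monte-Carlo error bars
comfortably inside the tolerances being checked.
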