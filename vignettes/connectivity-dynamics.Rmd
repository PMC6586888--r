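---
title: "Comparing connectivity dynamics across slow hemodynamic and multiband electrophysiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing connectivity dynamics across slow hemodynamic and multiband electrophysiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

## The scientific problem

Resting-state functional connectivity (FC) measured from slow
hemodynamic (BOLD-like) signals is an indirect readout of neural
synchrony. A central question at mesoscale is which frequency bands of
the local field potential (LFP) the slow signal's connectivity — both
its *spatial profile* and its *temporal dynamics* — actually reflects.
`dynfc` implements the full analysis chain needed to ask that question
quantitatively on paired recordings from two cortical regions:

1. band-specific decomposition of multichannel LFP-like signals into the
   canonical delta through gamma bands;
2. Welch magnitude-squared coherence (MSC) between channels, seed-to-all
   coherence maps, and stimulus-evoked band-power-change maps;
3. elliptical Gaussian point-spread-function (PSF) fitting of activation
   and local-connectivity maps, summarized by FWHM and the half-maximum
   ellipse area;
4. sliding-window connectivity in both modalities (Pearson correlation
   for the slow signals, band-averaged MSC and band-limited-power
   correlation for the fast signals);
5. discretization of windowed connectivity into putative brain states, a
   Markov-chain view of their single-step transitions, and comparison of
   modalities by the two-sample Kolmogorov–Smirnov (K-S) distance
   between jump ECDFs;
6. Fourier decomposition of connectivity fluctuations into slow
   frequency bands.

Because the recordings such analyses are usually run on are not
publicly deposited, the package ships a first-class synthetic-data
module that generates inputs with the statistical structure every stage
assumes, making the whole chain testable end to end.

## The state-transition model of connectivity dynamics

The instantaneous degree of inter-regional correlation is treated as a
brain state. Correlations are estimated in a sliding window (default 60
s, stepped by 3 s — one imaging volume), Fisher z transformed, and
binned into `n_states = 50` equal steps, yielding a state sequence
$s_1, s_2, \dots$ Under a first-order Markov assumption the dynamics
are characterized by single-step transitions; the package summarizes
them by the empirical CDF of the signed jumps $s_{t+1} - s_t$. Two
modalities are compared by

$$D = \sup_v \left| F_a(v) - F_b(v) \right|,$$

the two-sample K-S statistic evaluated on the union of observed jump
values. $D$ is used as a distance (no p-value is attached): lower
values mean more similar single-step dynamics. Group inference across
runs uses paired Wilcoxon signed-rank tests.

Two resolution decisions deserve comment:

* **Binning domain.** The procedure nominally bins "z-scores from −1 to
  1", which is internally inconsistent because Fisher z is unbounded.
  We bin the bounded correlation scale $[-1, 1]$ directly (the z values
  are still computed and recorded); `bin_states(on = "z_clipped")`
  provides the alternative reading — z clipped to $[-1, 1]$ — for
  sensitivity analysis. Coherence-based series are binned on $[0, 1]$,
  so jump sizes are in comparable state units across modalities.
* **Jump ECDFs, not transition matrices.** The headline statistic
  compares distributions of jumps between states, not the full
  $50 \times 50$ transition structure; `transition_matrix_distance()`
  (Frobenius norm of empirical transition matrices) is available as a
  diagnostic.

## What the synthetic generator emulates

`generate_coupled_pair()` realizes a hidden Markov coupling path
$c(t) \in [-1, 1]$ (default: five levels $\pm0.9, \pm0.45, 0$, a
reflecting nearest-neighbour random walk with stay probability 0.5 and
a 30 s dwell step — a state change roughly once per minute, slow enough
for a 60 s window to track and frequent enough for ~15 transitions in a
15 min run). Both modalities are built from band-limited Gaussian
components mixed as

$$x_1 = \sqrt{|c|}\, z + \sqrt{1 - |c|}\, e_1, \qquad
  x_2 = \mathrm{sign}(c)\sqrt{|c|}\, z + \sqrt{1 - |c|}\, e_2,$$

which gives unit variance and instantaneous correlation exactly $c$.
The slow pair uses 0.01–0.1 Hz components sampled once per 3 s volume
(no hemodynamic-response convolution is modelled; the analyses under
study never deconvolve one). The fast pair sums one such component per
frequency band at 500 Hz.

**Fidelity semantics.** Each band follows an amplitude-scaled copy of
the path about the chain's stationary mean $\bar c$:

$$p_b(t) = \bar c + \phi_b\,\big(c(t) - \bar c\big),$$

with $\phi_b$ = `low_band_fidelity` for bands at or below 15 Hz (and
the broadband, which the low bands dominate) and `high_band_fidelity`
for bands above. $\phi_b = 1$ reproduces the path exactly; $\phi_b = 0$
freezes the band's coupling at its mean, so its windowed connectivity
carries estimator noise but no dynamics. We chose amplitude scaling
over the superficially natural alternative — an *independent*
realization of the same chain — deliberately: an independent path has
the identical jump distribution in expectation, so the K-S distance
could not discriminate it from the shared path at all, and the mean K-S
would not be monotone in fidelity. Scaling makes fidelity a true dial
from "same dynamics" to "no dynamics", which also matches the empirical
picture the analysis is designed to detect (high-band coherence varying
less).

`generate_lfp_grid()` produces electrode-grid recordings whose
pairwise expected band coherence decays as a Gaussian of distance with
a stated FWHM. Channels mix a dense lattice of shared band-limited
sources with Gaussian weights of width
$\sigma_w = \mathrm{FWHM} / (2\sqrt{2\ln 2})$; with unit-norm weight
rows, the coherence between two channels equals the squared cosine of
their weight vectors, which for a dense lattice is
$\exp(-4 \ln 2\, d^2 / \mathrm{FWHM}^2)$. The lattice pitch is
$\sigma_w/\sqrt 2$ and the lattice extends $3\sigma_w$ beyond the grid,
making the discrete sums indistinguishable from the continuum values
(trapezoid error below $10^{-8}$ relatively) and edge electrodes
statistically identical to interior ones. The calibration is verified
empirically in the tests: at distance FWHM/2 the estimated MSC is 0.5
within Monte-Carlo tolerance.

**What the generator does not emulate.** Scanner and physiological
artifacts (motion, drift, cardiorespiratory noise), spiking activity,
hemodynamic convolution and vascular point spread, anatomical
boundaries, and any slow drift in the *uncoupled* band's connectivity:
a zero-fidelity band's residual variation is white coherence-estimator
noise, so its fluctuation spectrum is comparatively broadband rather
than concentrated at the slowest frequencies as real high-band
coherence may be. Passing tests therefore certify the estimators and
the recovery of planted structure, not robustness to real-data
artifacts.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band table | 8 canonical bands, 1–150 Hz | Hz | conventional LFP partition; configurable via `lfp_bands()`/`frequency_band()` |
| filter | Chebyshev I, order 2, 0.5 dB ripple, forward–backward | — | zero phase; effective attenuation squared; ripple config-exposed (the procedure specifies only "second order, zero-phase Chebyshev type-1") |
| edge handling | reflect padding, 3 × fs/f_low samples | samples | lets the filter settle; padded span recorded in metadata |
| Welch MSC | 2 s Hann segments, 50 % overlap, mean removal | s | ≥ 60 averages on a 2 min rest run; all quoted tolerances assume these defaults |
| per-band coherence scalar | mean MSC over in-band bins | — | the reduction is not specified by the procedure; the band average is used everywhere downstream |
| sliding window | 60 s window, 3 s step | s | 60 s attenuates spurious variation while keeping slow features; 30 s offered for comparison |
| states | 50 bins on [−1, 1] (r) or [0, 1] (MSC) | — | 50 is conventional and not critical; edges half-open, top bin closed |
| r = ±1 clipping | 1 − 10⁻⁷ | — | keeps Fisher z finite |
| BLP envelope | analytic-signal magnitude, no extra smoothing | — | the 60 s window already integrates the envelope; pre-smoothing only correlates estimator noise across windows and masks dynamics contrasts. `smoothing_s` and a rectify-and-smooth variant remain available |
| stimulus power windows | seconds 10–30 of each 30 s on-block vs final 20 s of the preceding off period | s | onset transients bias steady-state power; the baseline is anchored to the block end (anchoring is otherwise unspecified) |
| slow percent change | 10 on-volumes vs last 7 of the 10 pre-onset volumes | volumes | "seven out of ten" is unspecified as to which seven; the last seven are closest to onset |
| PSF thresholds | 0.7 (centre of mass), 0.2 (profile floor) | fraction of max | standard activation-focus conventions |
| profile resampling | 0.10 mm (grid maps), 0.068 mm (imaging maps) | mm | mirrors the usual resampling resolutions; bilinear interpolation |
| area | π (FWHM_maj/2)(FWHM_min/2) | mm² | operationalized as the half-maximum ellipse area; the source analyses report "area" without a formula, so this definition is stated prominently |
| Gaussian fit | no offset term | — | maps are normalized and floored at 0.2; `offset = TRUE` available |
| fluctuation bands | <0.0025, 0.0025–0.005, 0.005–0.01, 0.01–0.02, >0.02 Hz | Hz | left-closed, right-open; top band extends to 1/(2 step); DC excluded from normalization |

## Numerical choices

* MSC values are clipped to 1 only when they exceed it by ≤ 10⁻¹², and
  the auto-spectra are computed through the same summation path as the
  cross-spectrum so that `msc(x, x)` is *exactly* 1.
* Zero-variance inputs (dead channels, constant windows) yield missing
  values that propagate — never silent zeros; missing states break jump
  counting and the number dropped is recorded.
* Gaussian fits run Levenberg–Marquardt first and fall back to direct
  BFGS least squares: the `nls` machinery rejects exactly zero-residual
  (noiseless) fits with a singular gradient.
* The fluctuation periodogram is untapered by default (a Hann taper is
  available) and satisfies Parseval against the population variance of
  the mean-removed windowed series to 10⁻⁹ relative.
* The paired Wilcoxon test uses the exact signed-rank distribution for
  ≤ 25 untied differences, full enumeration of the 2^m sign assignments
  for ≤ 15 tied ones (so an all-positive n = 9 contrast gives exactly
  p = 1/512 one-sided), and a tie-corrected normal approximation above;
  all-zero differences return p = 1 with a degeneracy flag.
* Every generator takes a mandatory seed and restores the caller's RNG
  state; equal seeds give bit-identical outputs, and a rerun of a full
  session writes byte-identical tables.

## Problem sizes used by the tests

The test-suite and acceptance runs use the study's native settings —
300 volumes at 3 s (281 windows of 60 s), 500 Hz fast sampling, 7 × 7
grids at 0.4 mm, 9 runs per group — but restrict multi-band group runs
to the two bands each directional contrast actually compares (delta or
theta vs gamma high) and use shorter per-band recordings (120 s) for
the spatial-extent sessions. The analysis scripts under `analysis/`
run wider band sets. These sizes are the package's own choice of
desk-scale defaults; all of them are configurable through
`session_config()`.

## Known limitations

* The K-S comparison sees only marginal jump distributions; two
  sequences with identical jump statistics but different temporal
  alignment are indistinguishable by design (the transition-matrix
  diagnostic partially addresses this).
* The spatial generator calibrates *expected* coherence; single-run
  seed maps carry estimator noise and a positive bias floor of roughly
  1/M at distant electrodes.
* Sequential 1-D profile fitting mirrors the described procedure but is
  statistically less efficient than the full 2-D fit
  (`fit_gaussian_2d()`, provided as a cross-check) and assumes the
  supplied major-axis direction is correct.
* Windowed estimates from 20-volume windows are noisy (effective
  degrees of freedom are further reduced by the 0.01–0.1 Hz
  autocorrelation), so state sequences from slow signals include
  substantial estimator jitter; group-level contrasts, not single-run
  values, are the meaningful output.
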