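---
title: "Scale-free analysis of resting-state EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-free analysis of resting-state EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalEEG)
```

## Overview

fractalEEG implements a complete scale-free (fractal) analysis chain for
multichannel resting-state EEG: simulation of signals with known scaling
exponents, a preprocessing chain, spectral measures, generalized Hurst
exponent estimation, a nonparametric statistical battery, and topographic
summaries. Because clinical EEG cohorts are rarely redistributable, the
package is built around a synthetic cohort generator whose scaling
properties are known exactly, so every stage of the chain can be validated
by parameter recovery rather than by fiat.

## The estimand: generalized Hurst exponents

For a series $X(t)$, the q-order structure function is

$$K_q(\tau) = \left\langle |X(t+\tau) - X(t)|^q \right\rangle_t .$$

For a self-similar process $K_q(\tau) \propto \tau^{qH(q)}$. `ghe()` fits
$\log K_q(\tau)$ against $\log \tau$ over $\tau = 1,\dots,\tau_{max}$ for an
ensemble of maximum lags ($\tau_{max} \in \{5,\dots,19\}$ samples by
default), divides each slope by $q$, and averages over the ensemble;
averaging over fit ranges damps the sensitivity of the estimate to the
exact cutoff. The mean regression $R^2$ is kept per estimate as a fit
diagnostic. A $q$-dependent $H(q)$ indicates multifractality; for a
monofractal self-similar path such as fractional Brownian motion (fBm),
$H(q)$ is flat and $H(2)$ estimates the path Hurst exponent.

Two conventions matter and are deliberately explicit:

* **Representation.** The estimator is applied to the series exactly as
  given. On a stationary increment series (noise scale, like fractional
  Gaussian noise) a structure-function or DFA-type estimator returns
  $H \in (0,1)$; on the integrated series (walk scale) the same estimator
  returns $H + 1$. Resting-state EEG analysed directly at the signal level
  behaves walk-like over short lags, which is the regime in which reported
  scaling exponents above unity arise. The package never integrates or
  differences internally; the caller chooses the representation, and
  results are labelled by estimator.
* **Threshold.** `classify_persistence()` compares an estimate with the
  conventional threshold $T = 0.5$: below it, anti-persistent (mean
  reverting, short memory); above it, persistent (the Hurst effect).
  Estimates within a configurable `tie_band` (default $\pm 0.01$) are
  labelled `threshold` instead of being forced to a side, since "close to
  0.5" has no canonical width.

`mfdfa()` provides the standard multifractal detrended fluctuation
analysis variant: profile integration, per-scale linear detrending of
non-overlapping segments taken from both ends of the series, and q-order
fluctuation functions $F_q(s) \propto s^{h(q)}$ on scales log-spaced from
16 samples to a quarter of the series. For stationary input $h(2)$ is the
Hurst exponent; for integrated input $h(2) = H + 1$. MFDFA and the
structure-function estimator agree on fGn/fBm within estimator noise,
which the test suite checks against an independent rescaled-range
implementation as well.

`windowed_hfd()` applies either estimator per channel, per 30 s window
(default starts 0, 30, ..., 150 s) and per frequency band, always including
the full-spectrum band. Estimation is preceded by anti-aliased decimation
to 500 Hz by default: lags of 1–19 samples at 5000 Hz would span only
0.2–3.8 ms, physiologically uninteresting and numerically fragile, whereas
at 500 Hz they span 2–38 ms. Decimation can be disabled.

## Synthetic data: what it emulates and what it does not

`generate_fgn()` draws exact fractional Gaussian noise by Davies–Harte
circulant embedding: the fGn autocovariance is embedded in a circulant
matrix, eigenvalues obtained by FFT, and a complex Gaussian vector shaped
accordingly, so samples have *exactly* the requested autocovariance. For
$H \in (0,1)$ the embedding is non-negative definite; a negative eigenvalue
is treated as an implementation bug (error), not silently truncated.
`generate_fbm_path()` integrates fGn into fBm; `generate_binomial_cascade()`
produces a multiplicative binomial measure with known scaling exponents
$\tau(q) = -\log_2(p^q + (1-p)^q)$, the positive control for
multifractality detection.

`generate_cohort()` builds a 23-subject cohort (9 controls `C`, 5
chronic-pain subjects without opioids `N`, 9 with opioids `O`, with the
corresponding sexes, handedness and ages) of 63-channel recordings. Each
channel is an independent fBm carrier at the subject's group-target Hurst
exponent scaled to a 10 µV SD, plus:

* narrow-band oscillations per physiological band (one randomly placed
  sinusoid per band and channel, slow amplitude modulation);
* optionally a 60 Hz mains sinusoid, a sub-0.2 Hz drift, and blink
  transients (400 ms raised cosine, 10× carrier SD, Poisson arrivals at
  0.2 events/s) projected through a frontal scalp template so ICA sees one
  spatially coherent ocular component.

Two generator choices deserve comment. First, the group-target Hurst
exponents are *free configuration parameters* (defaults C = 0.70,
N = 0.55, O = 0.72, chosen to give a clear recoverable group effect with
the no-opioid group lowest): real group means are outcomes of an
experiment, not inputs, and the generator makes no claim about them.
Second, oscillation amplitudes are anchored to the carrier's lag-10
*increment* SD (gains of a few percent by default), not to the path SD. The
structure-function fit lives at lags of a few to a few dozen samples, where
an fBm path's increments are orders of magnitude smaller than its overall
range; oscillations scaled to the path SD would swamp those increments and
destroy the scaling the estimators are supposed to recover. With
increment-anchored gains at the defaults, the configured group ordering
survives the full pipeline.

What the generator does **not** emulate: volume conduction and realistic
inter-channel correlation, non-stationarity across the recording,
heavy-tailed muscle artifacts, electrode pops, or any pharmacological
mechanism. Passing tests therefore demonstrate that the *pipeline
machinery* is correct (estimators recover known exponents; preprocessing
removes what it claims to remove; statistics are calibrated), not that any
particular neurophysiological effect exists in real data.

## Preprocessing

`apply_filters()` implements the conditioning chain — drift removal at
0.2 Hz, mains notch at 60 Hz, band-pass 1–45 Hz — with equiripple FIR
filters designed by the Parks–McClellan (Remez exchange) algorithm and
applied with zero phase. Three numerical points:

* **Zero-phase application.** Filters are applied via circular convolution
  with the kernel's autocorrelation (FFT-based, reflection-padded), which
  is exactly the forward–backward application: no group delay, squared
  magnitude response. Designs target 40 dB stopband attenuation and ~0.2%
  passband ripple single-pass (passbands weighted 10:1 in the exchange),
  so the effective response is ~80 dB / ~0.4%.
* **Sharp low edges are multirate.** A direct FIR high-pass at 0.2 Hz (or
  the 1 Hz band edge) needs tens of thousands of taps at EEG rates. The
  package instead estimates the sub-cutoff component with a true equiripple
  low-pass at a decimated rate (anti-aliased, staged by factors ≤ 10),
  interpolates it back, and subtracts. Because the subtracted component is
  by construction slow, the interpolation back to the native rate is
  essentially exact, and the fast content never leaves the native rate.
* **Design validation.** The Remez exchange in the `signal` package can
  fail to converge on narrow bands at high orders — sometimes loudly,
  sometimes by returning a numerically degenerate filter. Every design is
  therefore validated against its requested response on a dense frequency
  grid and the order reduced geometrically until a sound design is found
  (cap 500 taps). One consequence: at multi-kHz sampling rates the 60 Hz
  notch becomes undesignable and mains rejection is carried by the
  band-pass stopband instead (a warning is raised if the line frequency
  falls inside the passband); transition bands also widen with the rate.
  Practical analyses decimate before estimation anyway.

`rereference()` offers the exact average reference (column sums zero) and
`rest_approx`, average reference followed by a scalar spherical-head
correction (default 1.25). Full reference standardization toward an
infinity reference requires a lead-field matrix for the individual head;
with dense whole-scalp coverage on a three-shell spherical model the
standardized signal is approximately a constant rescaling of the average
reference, which is what the approximation implements — deterministic,
testable, and clearly labelled in provenance.

`remove_ocular_ica()` replaces visual inspection of independent components
with two reproducible criteria: the component scalp map must correlate
with a frontal (ocular) template at ≥ 0.7, and its time course must be
super-Gaussian (kurtosis ≥ 5 — blinks are sparse transients). FastICA is
run in deflation mode with per-component convergence tracking: on
synthetic data every non-blink source is Gaussian, a regime where a
rotation within the Gaussian subspace has no fixed point, so global
convergence criteria would always fail while the blink component itself
converges in a few tens of iterations. Only individually converged
components can be rejected; if nothing converges the input passes through
unchanged with a warning. The unmixing learned on band-passed data can be
applied to a second (wider-band) recording via `apply_to`, mirroring the
usual two-pass scheme.

One bookkeeping ambiguity is left explicit rather than resolved: the
conditioning band-passes at 1–45 Hz, yet band analyses extend gamma to
100 Hz. The pipeline records each stage's actual band in provenance, caps
the gamma edge at `0.45 * fs`, and leaves the choice of analysis band to
the caller.

## Spectral measures

`welch_psd()` averages Hann-tapered, 50%-overlapping modified
periodograms; an 8 s window gives exactly 0.125 Hz resolution. The density
is one-sided and Parseval-consistent (integral equals variance). The taper
and overlap are the conventional defaults — the method specification fixes
only the window duration — and are recorded in provenance. Band powers are
trapezoid integrals over delta (0.5–4), theta (4–8), alpha (8–13), beta
(14–30) and gamma (30–100 Hz), exactly additive over adjacent bands.
Spectral entropy is the Shannon entropy of the power spectrum restricted
to [0.5, 100] Hz and normalized to sum one,

$$SE = -\sum_f rPS(f) \log_2 rPS(f),$$

with $0 \log 0 = 0$; normalization to unit sum is the convention required
for the flat (white-noise) spectrum to attain the maximum $\log_2 N$.
Whether entropy is taken per channel or on the channel-mean (global) PSD
is exposed as a choice: both `welch_psd()` output and `global_psd()` feed
`spectral_entropy()` unchanged.

## Statistics

The battery mirrors the usual report layout for this kind of study:
Kruskal–Wallis across groups and factors (tie-corrected, chi-square
reference), Wilcoxon signed-rank (normal approximation with continuity
correction, zero differences dropped, tie-corrected variance), paired t,
a factorial fixed-effects ANOVA on window-level Hurst estimates with
type-II sums of squares and up to two-way interactions (subject retained
as a column for sensitivity analyses; a full mixed model is out of scope),
per-band Pearson correlations between Hurst exponents and band powers with
a Bonferroni-adjusted threshold, and 10-fold validation (seeded disjoint
exhaustive partition; the held-in mean evaluated against each held-out
fold). Alpha-band rows are flagged and excluded from inference — the alpha
rhythm's dominant power makes its band a known outlier — but retained in
the table. The electrode factor is coarsened to five scalp regions
(frontal, central, temporal, parietal, occipital) derived from 10–20 label
prefixes: 63 electrode levels would exhaust any desk-scale design. All
tests are two-sided.

Null calibration is part of the test suite: at 2,000 null replicates the
empirical type-I error of each test must lie within 0.05 ± 0.015, and the
Bonferroni family-wise error across five bands must not exceed 0.05.

## Reporting

`summarize_groups()` reports mean, min, max and sample (n−1) SD per group
(the SD convention is fixed here because figure captions rarely state
it). `topomap()` averages estimates per electrode and interpolates over
the scalp disc with Gaussian radial basis functions; the node mean is
removed before solving so a constant field maps to a constant surface, and
the surface reproduces electrode values at the nodes to numerical
tolerance. Figures are rendered to PNG *and* the interpolated grid is
written as CSV so figure content is numerically testable. The default
prefrontal electrode subset for frontal summaries is Fp1, Fpz, Fp2, AF7,
AF3, AFz, AF4, AF8 (configurable).

`run_pipeline()` executes simulate → preprocess → spectra → Hurst →
stats → report from a single YAML/list configuration, writing every table
as CSV plus a provenance JSON with all stage parameters and seeds. Output
is deterministic: identical configuration and seed give byte-identical
CSVs.

## Problem sizes and defaults

The full-scale acquisition geometry this pipeline targets is 63 channels
× 5000 Hz × 180 s ≈ 5.7 × 10⁷ samples per subject, 138 subject-windows
over the 23-subject cohort. The shipped default pipeline configuration
runs the same topology at reduced scale (8 channels, 100 Hz) so a complete
end-to-end run takes seconds; estimator validation uses series of
1.5 × 10⁵ samples (20 seeds per condition), where the structure-function
estimator recovers generator exponents with |bias| < 0.03 and SD < 0.05 —
these are the sizes the test suite and the acceptance script use. Scaling
the configuration up to the full geometry changes only runtime.

## Known limitations

* Exponent estimates on band-limited signals depend on the relation
  between oscillation periods and the lag window: when a rhythm's period
  falls inside the τ range, its structure function plateaus and biases the
  slope downward. At the default decimation (500 Hz, τ ≤ 38 ms) all
  classical EEG rhythms are slower than the lag window, but analyses at
  very low sampling rates should interpret absolute H values with care
  (group *contrasts* are much more robust).
* The REST approximation is a scalar correction, not a lead-field
  computation.
* `signal::remez` order limits mean transition bands widen with sampling
  rate; at multi-kHz rates the notch falls back to the band-pass stopband.
* The synthetic cohort has independent channels; spatial statistics on it
  (e.g. topographic smoothness) are not realistic, only the per-channel
  scaling content is.
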