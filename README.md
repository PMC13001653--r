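# fractalEEG

Scale-free (fractal) analysis of multichannel resting-state EEG in R.

Resting-state EEG carries long-range temporal correlations: its q-order
increment moments scale as power laws, and the scaling exponent — the
generalized Hurst exponent H(q) — summarizes the signal's memory and
complexity. H below the 0.5 threshold marks anti-persistent (mean
reverting) dynamics, H above it the persistent "Hurst effect", and a
q-dependent H(q) marks multifractality. Differences in these exponents
between clinical groups (here: healthy controls `C`, chronic-pain
patients without opioid medication `N`, and chronic-pain patients on
opioids `O`) have been proposed as an EEG biomarker, which makes a
carefully validated, fully reproducible estimation pipeline worth having
as a package.

fractalEEG provides that pipeline end to end, for researchers analysing
resting-state EEG and for methodologists who want estimators they can
validate against known ground truth:

* **Synthetic ground truth** — exact fractional Gaussian noise / fractional
  Brownian motion via Davies–Harte circulant embedding, multiplicative
  binomial cascades with closed-form ζ(q), and a 23-subject synthetic EEG
  cohort generator (63-channel, 5000 Hz, 180 s geometry; configurable
  group Hurst targets; mains, drift and blink artifacts).
* **Preprocessing** — zero-phase equiripple (Parks–McClellan) FIR chain
  (0.2 Hz drift removal, 60 Hz notch, 1–45 Hz band-pass), average or
  approximate-REST re-referencing, FastICA ocular artifact removal with
  automated component rejection, band extraction, 30 s windowing; readers
  and writers for BrainVision (.vhdr/.vmrk/.eeg) and EDF.
* **Spectral measures** — Welch PSD (8 s windows, 0.125 Hz resolution),
  global PSD, band powers (delta–gamma), spectral entropy
  SE = −Σ rPS(f) log₂ rPS(f).
* **The core estimators** — `ghe()` fits K_q(τ) = ⟨|X(t+τ)−X(t)|^q⟩ ∝
  τ^{qH(q)} over an ensemble of lag ranges; `mfdfa()` is the multifractal
  DFA variant. Both return a classed fit object with `print`, `summary`,
  `coef` and `plot` methods. Plus persistence classification against
  T = 0.5 and shuffle surrogates.
* **Statistics** — Kruskal–Wallis, Wilcoxon signed-rank (z approximation),
  paired t, factorial n-way ANOVA (type II) with interaction surfaces,
  per-band Pearson correlation with Bonferroni correction, k-fold
  (k = 10) validation; alpha-band rows excluded from inference.
* **Reporting** — group summaries (mean/range/SD), radial-basis
  topographic scalp maps (PNG + numeric grid CSV), and a one-call
  `run_pipeline()` orchestrator with YAML configuration and full
  provenance.

## Worked example

Estimate H(q) on a random-walk-scale series with known exponent 0.7:

```r
library(fractalEEG)

walk <- generate_fbm_path(fgn_spec(n_samples = 150000, hurst = 0.7, seed = 1))
fit <- ghe(walk, q = 1:5)
summary(fit)
#> <generalized Hurst exponent fit> n = 150000
#>  q  hurst fit_r2
#>  1 0.7024      1
#>  2 0.7014      1
#>  3 0.7008      1
#>  4 0.7004      1
#>  5 0.7004      1
#> H(2) = 0.7014 (persistent); H(q) spread over q: 0.0020
```

H(2) recovers the generator exponent to 0.001 and H(q) is flat — the
monofractal signature. A binomial cascade (p = 0.7), by contrast, is
multifractal: H(q) falls with q, tracking the analytic
(τ(q)+1)/q = (1 − log₂(0.7^q + 0.3^q))/q:

```r
cascade <- generate_binomial_cascade(14, weight_p = 0.7, seed = 1)
round(coef(ghe(cumsum(cascade), q = 1:5)), 3)
#>  H(1)  H(2)  H(3)  H(4)  H(5)
#> 1.000 0.880 0.796 0.739 0.700
```

A miniature cohort run, from simulation through preprocessing to group
summaries (8 channels at 100 Hz to keep it instant; the geometry scales):

```r
spec <- cohort_spec(n_channels = 8, fs = 100, duration_s = 180,
                    line_noise = FALSE, seed = 1)
rec <- generate_recording(spec, spec$subjects[1, ])   # subject C1
clean <- rereference(remove_ocular_ica(apply_filters(rec), seed = 1)$recording)
hfd <- windowed_hfd(clean, q = 2)                     # 8 channels x 6 windows
summarize_groups(hfd_table(hfd, spec$subjects))
#>   group      mean       min      max         sd  n
#> 1     C 0.6036771 0.5574433 0.638292 0.01762482 48
```

The group mean sits below the configured target (0.70) by a known,
documented mechanism — band-limited oscillations and the 1 Hz band edge
bias absolute exponents downward at low sampling rates — while group
*contrasts* are preserved; see the methods vignette
(`vignettes/fractal-eeg-methods.Rmd`).

The whole chain (simulate → preprocess → spectra → HFD → stats → maps) is
one call:

```r
run_pipeline(pipeline_config(), out_dir = "pipeline_out", seed = 1)
```

which writes `cohort.csv`, `spectra.csv`, `hfd.csv` (138 subject-windows),
`group_summary.csv`, `stats/*.csv`, per-group topographic maps
(`topo_C.png` + numeric grids) and `provenance.json`. A YAML-driven CLI
wrapper lives at `inst/cli/run_pipeline.R`, with a commented example
configuration in `inst/extdata/pipeline_example.yaml`.

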