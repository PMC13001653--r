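#' Welch power spectral density
#'
#' Averaged modified periodograms: the signal is cut into segments of
#' `window_s` seconds with fractional overlap `overlap_frac`, each segment
#' is Hann-tapered and its periodogram computed; the per-channel PSD is the
#' segment average, scaled as a one-sided density (uV^2/Hz) so that the
#' integral over `[0, fs/2]` equals the signal variance (Parseval). The
#' frequency spacing is exactly `1/window_s` (0.125 Hz for the default
#' 8 s window).
#'
#' @param rec an [recording()].
#' @param window_s segment duration in seconds (default 8).
#' @param overlap_frac fractional overlap between segments (default 0.5).
#' @param demean subtract each segment's mean before tapering (default
#'   TRUE).
#' @return Object of class `psd_result`: `freqs` (Hz), `psd` (channels x
#'   frequencies), `window_s`, `resolution_hz`, `fs`, `channel_labels`.
#' @export
welch_psd <- function(rec, window_s = 8, overlap_frac = 0.5, demean = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  nper <- round(window_s * fs)
  n <- ncol(rec$samples)
  if (n < nper)
    stop("recording (", n / fs, " s) shorter than one Welch window (",
         window_s, " s)")
  step <- max(1L, round(nper * (1 - overlap_frac)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nper - 1) / nper))  # periodic Hann
  u <- sum(w^2)
  nfreq <- nper %/% 2L + 1L
  scale <- 1 / (fs * u)

  psd <- matrix(0, nrow(rec$samples), nfreq)
  for (s0 in starts) {
    seg <- rec$samples[, s0:(s0 + nper - 1L), drop = FALSE]
    if (demean) seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, w, "*")
    ft <- t(apply(seg, 1L, stats::fft))
    p <- Mod(ft[, seq_len(nfreq), drop = FALSE])^2 * scale
    # one-sided: double all bins except DC and Nyquist
    dbl <- 2:(nfreq - if (nper %% 2L == 0L) 1L else 0L)
    p[, dbl] <- 2 * p[, dbl]
    psd <- psd + p
  }
  psd <- psd / length(starts)
  structure(list(freqs = (seq_len(nfreq) - 1) / window_s,
                 psd = psd, window_s = window_s,
                 resolution_hz = 1 / window_s, fs = fs,
                 channel_labels = rec$channel_labels),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d channel(s), %d bins, 0-%.6g Hz at %.6g Hz resolution\n",
              nrow(x$psd), length(x$freqs), max(x$freqs), x$resolution_hz))
  invisible(x)
}

#' Global power spectral density
#'
#' Arithmetic mean of the per-channel densities on the same frequency grid.
#'
#' @param psd a `psd_result` from [welch_psd()].
#' @return A single-channel `psd_result` labelled `"global"`.
#' @export
global_psd <- function(psd) {
  stopifnot(inherits(psd, "psd_result"))
  out <- psd
  out$psd <- matrix(colMeans(psd$psd), 1L)
  out$channel_labels <- "global"
  out
}

#' Band power by trapezoidal integration
#'
#' Integrates each channel's density over `[low_hz, high_hz]` with the
#' trapezoid rule; band edges falling between grid points are handled by
#' linear interpolation, so power is exactly additive over adjacent bands
#' sharing an edge.
#'
#' @param psd a `psd_result`.
#' @param band a [band_definition()].
#' @return Named numeric vector, one power (uV^2) per channel.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_result"), inherits(band, "band_definition"))
  f <- psd$freqs
  lo <- band$low_hz; hi <- min(band$high_hz, max(f))
  if (lo >= max(f) || hi <= min(f) || lo >= hi)
    stop("band [", band$low_hz, ", ", band$high_hz,
         "] Hz does not intersect the frequency grid")
  inside <- f > lo & f < hi
  pw <- apply(psd$psd, 1L, function(p) {
    pl <- stats::approx(f, p, xout = lo)$y
    ph <- stats::approx(f, p, xout = hi)$y
    fg <- c(lo, f[inside], hi)
    pg <- c(pl, p[inside], ph)
    sum(diff(fg) * (pg[-1] + pg[-length(pg)]) / 2)
  })
  stats::setNames(pw, psd$channel_labels)
}

#' Spectral entropy of the normalized power spectrum
#'
#' Shannon entropy (bits) of the relative power spectrum: the density is
#' restricted to `[fmin, fmax]`, normalized to sum to one, and
#' \eqn{SE = -\sum rPS(f)\, \log_2 rPS(f)} with the convention
#' \eqn{0 \log 0 = 0}. A flat (white-noise) spectrum over N bins attains
#' the maximum \eqn{\log_2 N}; a single-bin spectrum gives 0. SE is
#' invariant to overall power rescaling.
#'
#' @param psd a `psd_result`.
#' @param fmin,fmax frequency range in Hz (defaults 0.5 and 100).
#' @return Object of class `spectral_entropy_result`: `se_bits` (named per
#'   channel), `fmin`, `fmax`, `n_bins`.
#' @export
spectral_entropy <- function(psd, fmin = 0.5, fmax = 100) {
  stopifnot(inherits(psd, "psd_result"))
  sel <- psd$freqs >= fmin & psd$freqs <= fmax
  if (sum(sel) < 2L) stop("fewer than 2 frequency bins inside [fmin, fmax]")
  se <- apply(psd$psd[, sel, drop = FALSE], 1L, function(p) {
    tot <- sum(p)
    if (tot <= 0) stop("all-zero power in the entropy range")
    r <- p / tot
    r <- r[r > 0]
    -sum(r * log2(r))
  })
  structure(list(se_bits = stats::setNames(se, psd$channel_labels),
                 fmin = fmin, fmax = fmax, n_bins = sum(sel)),
            class = "spectral_entropy_result")
}

#' Tidy per-band spectral summary of a recording
#'
#' Convenience wrapper producing a long table of band powers and spectral
#' entropy per channel.
#'
#' @param rec an [recording()].
#' @param bands named list of band definitions (default [eeg_bands()]
#'   without `full`).
#' @param window_s Welch window, seconds.
#' @return Data frame with columns `subject_id`, `channel`, `band`,
#'   `power`, `se_bits`.
#' @export
spectral_summary <- function(rec, bands = NULL, window_s = 8) {
  psd <- welch_psd(rec, window_s = window_s)
  if (is.null(bands)) {
    bands <- eeg_bands(rec$fs)
    bands$full <- NULL
  }
  se <- spectral_entropy(psd, fmin = 0.5, fmax = min(100, 0.999 * rec$fs / 2))
  sid <- if (!is.null(rec$meta)) rec$meta$subject_id else NA_character_
  do.call(rbind, lapply(names(bands), function(b) {
    data.frame(subject_id = sid, channel = psd$channel_labels, band = b,
               power = unname(band_power(psd, bands[[b]])),
               se_bits = unname(se$se_bits), stringsAsFactors = FALSE)
  }))
}
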