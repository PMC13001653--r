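#' Physiological EEG band definitions
#'
#' Standard band edges used throughout the pipeline: delta 0.5-4, theta 4-8,
#' alpha 8-13, beta 14-30 and gamma 30-100 Hz, plus `full` for the
#' band-passed full-spectrum signal. The gamma upper edge is capped at
#' `0.45 * fs` when a sampling rate is supplied, so the band stays below
#' Nyquist for decimated data.
#'
#' @param fs optional sampling rate used to cap the gamma band.
#' @return Named list of band definitions (`name`, `low_hz`, `high_hz`).
#' @export
eeg_bands <- function(fs = NULL) {
  b <- list(
    delta = band_definition("delta", 0.5, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 14, 30),
    gamma = band_definition("gamma", 30, 100),
    full  = band_definition("full", 0.5, 100)
  )
  if (!is.null(fs)) {
    cap <- 0.45 * fs
    for (nm in names(b)) {
      b[[nm]]$high_hz <- min(b[[nm]]$high_hz, cap)
      if (b[[nm]]$low_hz >= b[[nm]]$high_hz) b[[nm]] <- NULL
    }
  }
  b
}

#' Frequency band definition
#' @param name band name.
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @return List of class `band_definition`.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("require 0 < low_hz < high_hz")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' Analysis window specification
#'
#' Non-overlapping half-open windows `[start, start + length)` in seconds.
#' The default -- six 30 s windows starting at 0, 30, ..., 150 s -- tiles a
#' 180 s resting-state recording exactly.
#'
#' @param length_s window length, seconds.
#' @param start_times_s window start times, seconds.
#' @return List of class `window_spec`.
#' @export
window_spec <- function(length_s = 30, start_times_s = seq(0, 150, by = 30)) {
  st <- sort(start_times_s)
  if (length(st) > 1 && any(diff(st) < length_s - 1e-9))
    stop("windows must not overlap")
  structure(list(length_s = length_s, start_times_s = st),
            class = "window_spec")
}

# --- equiripple FIR design -------------------------------------------------

# Evaluate |H(f)| of an FIR at normalized frequencies (1 = Nyquist)
fir_gain <- function(h, f_norm) {
  k <- seq_along(h) - 1
  vapply(f_norm, function(fn)
    Mod(sum(h * exp(-1i * pi * fn * k))), numeric(1))
}

# The remez exchange can fail to converge at high orders on narrow bands --
# sometimes raising an error, sometimes silently returning a numerically
# degenerate filter. Designs are therefore validated against the requested
# response at band midpoints and the order reduced geometrically until a
# sound design is found.
remez_robust <- function(n, f, a, min_order = 50L) {
  n <- max(n, min_order)
  # dense probe grid over every requested band (spiky failed designs can
  # look fine at isolated frequencies)
  probes <- do.call(rbind, lapply(seq(1, length(f) - 1, by = 2), function(i) {
    fr <- seq(f[i], f[i + 1], length.out = 64)
    cbind(fr, a[i])
  }))
  # weight passbands 10:1 so passband ripple stays an order of magnitude
  # below stopband ripple (zero-phase application squares the response, so
  # passband error doubles while stopband attenuation doubles in dB)
  w <- ifelse(a[seq(1, length(a), by = 2)] == 1, 10, 1)
  repeat {
    h <- try(signal::remez(n, f, a, w), silent = TRUE)
    if (!inherits(h, "try-error")) {
      h <- as.numeric(h)
      g <- fir_gain(h, probes[, 1])
      ok <- all(is.finite(h)) &&
        all(abs(g[probes[, 2] == 1] - 1) < 0.02) &&
        all(g[probes[, 2] == 0] < 0.07) &&
        max(g) < 1.1
      if (ok) return(h)
    }
    if (n <= min_order)
      stop("equiripple design failed even at order ", min_order)
    n <- max(min_order, floor(n * 0.8))
    if (n %% 2L == 1L) n <- n + 1L
  }
}

# Parks-McClellan design with order chosen by the harris approximation
# N ~ fs * atten_db / (22 * transition_hz), capped to keep design tractable.
design_remez <- function(fs, f_pass, f_stop, type = c("low", "high"),
                         atten_db = 40, max_order = 500L) {
  type <- match.arg(type)
  trans <- abs(f_stop - f_pass)
  n <- ceiling(fs * atten_db / (22 * trans))
  n <- min(n, max_order)
  if (n %% 2L == 1L) n <- n + 1L  # type-I works for both low and high pass
  ny <- fs / 2
  if (type == "low") {
    f <- c(0, f_pass / ny, f_stop / ny, 1); a <- c(1, 1, 0, 0)
  } else {
    f <- c(0, f_stop / ny, f_pass / ny, 1); a <- c(0, 0, 1, 1)
  }
  remez_robust(n, f, a)
}

# Low-pass at `cut` Hz with the transition width widened, when necessary,
# to what the order cap can actually deliver at this sampling rate.
design_lowcut <- function(fs, cut, atten_db = 40, max_order = 500L) {
  ny <- fs / 2
  trans <- max(min(5, 0.9 * (ny - cut)), fs * atten_db / (22 * max_order))
  trans <- min(trans, 0.995 * ny - cut)
  if (trans <= 0) stop("cutoff too close to Nyquist")
  design_remez(fs, f_pass = cut, f_stop = cut + trans, type = "low",
               atten_db = atten_db, max_order = max_order)
}

design_notch <- function(fs, f0, half_width = 1, trans = 1.5,
                         atten_db = 40, max_order = 500L) {
  ny <- fs / 2
  trans <- max(trans, fs * atten_db / (22 * max_order))
  n <- min(ceiling(fs * atten_db / (22 * trans)), max_order)
  if (n %% 2L == 1L) n <- n + 1L
  f <- c(0, (f0 - half_width - trans) / ny, (f0 - half_width) / ny,
         (f0 + half_width) / ny, (f0 + half_width + trans) / ny, 1)
  a <- c(1, 1, 0, 0, 1, 1)
  remez_robust(n, f, a)
}

# Zero-phase FIR filtering of each matrix row: the signal is reflected at
# both ends, then circularly convolved (via FFT) with the autocorrelation of
# the filter kernel, which has exactly zero phase and squared magnitude
# response. Equivalent to forward-backward application of the kernel.
fir_zero_phase <- function(x, h) {
  if (is.vector(x)) return(drop(fir_zero_phase(matrix(x, 1), h)))
  L <- length(h)
  n <- ncol(x)
  pad <- min(L, n - 1L)
  # reflect around the end samples to suppress edge transients
  left <- x[, pad:1, drop = FALSE]
  right <- x[, n:(n - pad + 1L), drop = FALSE]
  xp <- cbind(2 * x[, 1] - left, x, 2 * x[, n] - right)
  m <- ncol(xp)
  nfft <- stats::nextn(m + 2L * L, 2)
  H2 <- Mod(stats::fft(c(h, numeric(nfft - L))))^2
  out <- t(apply(xp, 1L, function(row) {
    Y <- stats::fft(c(row, numeric(nfft - m))) * H2
    Re(stats::fft(Y, inverse = TRUE)) / nfft
  }))
  # zero-phase: no group delay to compensate; drop the reflection padding
  out[, (pad + 1L):(pad + n), drop = FALSE]
}

# Drift (sub-`cut` Hz) removal as a multirate zero-phase FIR high-pass:
# the drift is estimated by an equiripple low-pass (passband [0, cut/2],
# stopband from cut) applied at a decimated rate where the design is
# well-conditioned, interpolated back to the native rate, and subtracted.
# A direct narrow high-pass at e.g. 5000 Hz would need > 10^5 taps; the
# decimated design is the same filter implemented efficiently.
remove_drift <- function(x, fs, cut, max_order = 500L) {
  if (is.vector(x)) return(drop(remove_drift(matrix(x, 1), fs, cut, max_order)))
  target <- 40 * cut  # internal rate; Nyquist comfortably above `cut`
  if (fs <= target * 2) {
    h <- design_remez(fs, f_pass = cut / 2, f_stop = cut, type = "low",
                      max_order = max_order)
    return(x - fir_zero_phase(x, h))
  }
  dec <- decimate_series(x, fs, target)
  h <- design_remez(dec$fs, f_pass = cut / 2, f_stop = cut, type = "low",
                    max_order = max_order)
  low <- fir_zero_phase(dec$x, h)
  t_dec <- (seq_len(ncol(low)) - 1) * (fs / dec$fs)  # in native samples
  t_full <- seq_len(ncol(x)) - 1
  drift <- t(apply(low, 1L, function(row)
    stats::approx(t_dec, row, xout = t_full, rule = 2)$y))
  x - drift
}

# Band-pass as a cascade of a sharp multirate low-edge high-pass
# (subtract-lowpass, exact at the native rate) and a full-rate equiripple
# low-pass for the high edge. Both stages are Parks-McClellan designs at
# orders the exchange algorithm handles reliably, at any sampling rate.
bandpass_apply <- function(x, fs, low, high, max_order = 500L) {
  x <- remove_drift(x, fs, low, max_order = max_order)
  h <- design_lowcut(fs, high, max_order = max_order)
  fir_zero_phase(x, h)
}

#' Condition a recording: drift, mains and band-pass filtering
#'
#' Applies the standard resting-state conditioning chain with equiripple
#' (Parks-McClellan) FIR filters, each applied with zero phase: a high-pass
#' at `drift_cut` removing physiological drift (heartbeat, respiration,
#' electrode drift), a notch at `line_hz` removing mains interference, and a
#' band-pass from `band_low` to `band_high`. Zero-phase application squares
#' each filter's magnitude response, so the effective stopband attenuation
#' is twice the 40 dB single-pass design target.
#'
#' @param rec an [recording()].
#' @param band_low,band_high band-pass edges, Hz (defaults 1 and 45).
#' @param drift_cut drift high-pass cutoff, Hz (default 0.2).
#' @param line_hz mains frequency, Hz (default 60); skipped when at or above
#'   Nyquist or outside the pass band's stop region is irrelevant.
#' @param max_order cap on individual FIR orders.
#' @return Filtered recording, same shape, with provenance appended.
#' @export
apply_filters <- function(rec, band_low = 1, band_high = 45, drift_cut = 0.2,
                          line_hz = 60, max_order = 500L) {
  stopifnot(inherits(rec, "eeg_recording"))
  ny <- rec$fs / 2
  if (band_high >= ny) stop("band_high must be below Nyquist (", ny, " Hz)")
  if (band_low >= band_high) stop("band_low must be below band_high")
  x <- rec$samples
  if (ncol(x) < 3L * (max_order + 1L))
    stop("recording shorter than 3x the maximum filter length (",
         3L * (max_order + 1L), " samples needed)")

  x <- remove_drift(x, rec$fs, drift_cut, max_order = max_order)

  notch_applied <- FALSE
  if (!is.null(line_hz) && is.finite(line_hz) && line_hz < 0.95 * ny) {
    # at very high sampling rates the narrow notch can be undesignable; the
    # band-pass stopband then carries the mains rejection whenever the line
    # frequency lies above the passband
    h_nt <- tryCatch(design_notch(rec$fs, line_hz, max_order = max_order),
                     error = function(e) NULL)
    if (!is.null(h_nt)) {
      x <- fir_zero_phase(x, h_nt)
      notch_applied <- TRUE
    } else if (line_hz <= band_high) {
      warning("mains notch design failed at fs = ", rec$fs,
              " Hz and ", line_hz, " Hz lies inside the passband; ",
              "line noise is not removed")
    }
  }

  x <- bandpass_apply(x, rec$fs, band_low, band_high, max_order = max_order)

  out <- rec
  out$samples <- x
  rownames(out$samples) <- rec$channel_labels
  add_provenance(out, "apply_filters",
                 list(band_low = band_low, band_high = band_high,
                      drift_cut = drift_cut, line_hz = line_hz,
                      notch_applied = notch_applied,
                      design = "remez", zero_phase = TRUE))
}

#' Re-reference a recording
#'
#' `average`: subtracts the instantaneous mean across channels, so the
#' column sums are exactly zero. `rest_approx`: average reference followed
#' by a scalar spherical-head correction factor approximating reference
#' standardization toward an infinity reference; with a three-shell
#' spherical head and dense whole-scalp coverage the standardized signal is
#' approximately the average-referenced signal scaled by a constant
#' (default 1.25), since the true reference offset is a spatial constant
#' recovered only up to the head model. The applied transform is recorded
#' in provenance so it can be undone.
#'
#' @param rec an [recording()] with at least 2 channels.
#' @param method `"average"` (default) or `"rest_approx"`.
#' @param rest_scale scalar gain for `rest_approx`.
#' @return Re-referenced recording.
#' @export
rereference <- function(rec, method = c("average", "rest_approx"),
                        rest_scale = 1.25) {
  stopifnot(inherits(rec, "eeg_recording"))
  method <- match.arg(method)
  if (nrow(rec$samples) < 2L) stop("re-referencing needs >= 2 channels")
  mu <- colMeans(rec$samples)
  out <- rec
  out$samples <- sweep(rec$samples, 2L, mu)
  if (method == "rest_approx") out$samples <- rest_scale * out$samples
  add_provenance(out, "rereference",
                 list(method = method,
                      scale = if (method == "rest_approx") rest_scale else 1))
}

#' Extract one frequency band from a recording
#'
#' Band-pass copy of the recording using a zero-phase equiripple FIR. The
#' `full` band is returned unchanged (it is defined by [apply_filters()]).
#'
#' @param rec an [recording()].
#' @param band a [band_definition()].
#' @param max_order FIR order cap.
#' @return Band-limited recording.
#' @export
extract_band <- function(rec, band, max_order = 500L) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(band, "band_definition"))
  if (band$name == "full") {
    return(add_provenance(rec, "extract_band", list(band = "full")))
  }
  ny <- rec$fs / 2
  if (band$high_hz >= ny)
    stop("band '", band$name, "' upper edge ", band$high_hz,
         " Hz is at/above Nyquist (", ny, " Hz)")
  out <- rec
  out$samples <- bandpass_apply(rec$samples, rec$fs, band$low_hz,
                                band$high_hz, max_order = max_order)
  rownames(out$samples) <- rec$channel_labels
  add_provenance(out, "extract_band",
                 list(band = band$name, low_hz = band$low_hz,
                      high_hz = band$high_hz))
}

#' Cut a recording into analysis windows
#'
#' Half-open sample ranges `[start * fs, (start + length) * fs)`; with the
#' default specification a 180 s recording is partitioned exactly into six
#' 30 s windows with no sample lost or duplicated.
#'
#' @param rec an [recording()].
#' @param spec a [window_spec()].
#' @return List of windowed recordings; each carries a `window_start_s`
#'   field.
#' @export
segment_windows <- function(rec, spec = window_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "window_spec"))
  n <- ncol(rec$samples)
  lapply(spec$start_times_s, function(s0) {
    i0 <- round(s0 * rec$fs) + 1L
    i1 <- round((s0 + spec$length_s) * rec$fs)
    if (i1 > n)
      stop("window [", s0, ", ", s0 + spec$length_s,
           ") s exceeds recording end (", n / rec$fs, " s)")
    w <- rec
    w$samples <- rec$samples[, i0:i1, drop = FALSE]
    w$window_start_s <- s0
    add_provenance(w, "segment",
                   list(start_s = s0, length_s = spec$length_s))
  })
}
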