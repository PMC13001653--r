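#' q-order structure function of a time series
#'
#' \eqn{K_q(\tau) = \frac{1}{n-\tau}\sum_t |X(t+\tau) - X(t)|^q}, the
#' absolute q-order moment of increments at lag `tau` (in samples). For a
#' self-similar series \eqn{K_q(\tau) \propto \tau^{qH(q)}}, which is the
#' scaling relation the generalized Hurst estimator fits. `tau = 0` returns
#' 0 by convention. Exactly invariant under time reversal and under affine
#' maps up to the scale factor `|a|^q`.
#'
#' @param series numeric vector.
#' @param q positive moment order.
#' @param tau lag in samples, `0 <= tau < length(series)`.
#' @return Non-negative scalar.
#' @export
structure_function <- function(series, q, tau) {
  n <- length(series)
  if (tau >= n) stop("tau must be smaller than the series length")
  if (tau == 0) return(0)
  d <- series[(1 + tau):n] - series[1:(n - tau)]
  mean(abs(d)^q)
}

#' Anti-aliased decimation
#'
#' Low-pass filters (zero-phase equiripple FIR, cutoff at 40% of the target
#' rate) and subsamples. Large rate reductions are performed in stages of
#' at most a factor of 10 so every anti-alias design has a proportional,
#' well-conditioned transition band. Returns the input unchanged when
#' `fs <= target_hz`.
#'
#' @param x numeric vector or channels x time matrix.
#' @param fs input sampling rate, Hz.
#' @param target_hz desired output rate, Hz.
#' @return List with `x` (decimated data) and `fs` (achieved rate).
#' @export
decimate_series <- function(x, fs, target_hz) {
  vec <- is.vector(x)
  if (vec) x <- matrix(x, 1)
  while (floor(fs / target_hz) > 1L) {
    fac <- min(floor(fs / target_hz), 10L)
    new_fs <- fs / fac
    h <- design_remez(fs, f_pass = 0.4 * new_fs, f_stop = 0.5 * new_fs,
                      type = "low", max_order = 500L)
    x <- fir_zero_phase(x, h)[, seq(1L, ncol(x), by = fac), drop = FALSE]
    fs <- new_fs
  }
  list(x = if (vec) drop(x) else x, fs = fs)
}

#' Generalized Hurst exponent by structure-function scaling
#'
#' Fits the scaling relation \eqn{K_q(\tau) \propto \tau^{qH(q)}} for each
#' moment order in `q`: for every maximum lag in `tau_max_range`,
#' \eqn{\log K_q(\tau)} is regressed on \eqn{\log \tau} over
#' `tau = tau_min .. tau_max` and the slope divided by q; H(q) is the mean
#' over the tau_max ensemble (averaging over fit ranges reduces the
#' sensitivity of the estimate to the exact cutoff), with the mean
#' regression R-squared kept as a fit diagnostic. A q-dependent H indicates
#' multifractality; for monofractal self-similar series (e.g. fractional
#' Brownian motion) H(q) is flat and H(2) estimates the path Hurst
#' exponent.
#'
#' The estimator is applied to the series exactly as given -- no internal
#' integration or differencing -- so the caller controls whether noise-scale
#' (increment) or walk-scale (path) scaling is estimated.
#'
#' @param series numeric vector (length >= 100 after decimation).
#' @param q vector of positive moment orders (default 1:5).
#' @param tau_min smallest lag in samples.
#' @param tau_max_range vector of largest lags; one fit per element.
#' @param fs optional sampling rate; needed only when `decimate_to_hz` is
#'   set.
#' @param decimate_to_hz optional target rate for anti-aliased decimation
#'   before estimation (`NULL` = none).
#' @return Object of class `ghe_fit` with components `table` (data frame
#'   `q`, `hurst`, `fit_r2`), `q`, `tau_min`, `tau_max_range`, `n`,
#'   `estimator = "ghe"`.
#' @examples
#' walk <- cumsum(rnorm(5000))
#' fit <- ghe(walk)
#' coef(fit)            # H(q)
#' @export
ghe <- function(series, q = 1:5, tau_min = 1L, tau_max_range = 5:19,
                fs = NULL, decimate_to_hz = NULL) {
  if (!is.null(decimate_to_hz)) {
    if (is.null(fs)) stop("fs required for decimation")
    dec <- decimate_series(series, fs, decimate_to_hz)
    series <- dec$x
  }
  n <- length(series)
  if (n < 100L) stop("series too short (< 100 samples) for GHE estimation")
  if (any(q <= 0)) stop("all q must be positive")
  if (min(tau_max_range) < 2L * tau_min)
    stop("tau_max must be at least 2 * tau_min")
  if (stats::sd(series) == 0) stop("degenerate series: zero variance")

  taus <- tau_min:max(tau_max_range)
  lk <- matrix(NA_real_, length(q), length(taus))
  for (j in seq_along(taus)) {
    d <- abs(series[(1 + taus[j]):n] - series[1:(n - taus[j])])
    for (i in seq_along(q)) lk[i, j] <- log(mean(d^q[i]))
  }
  lt <- log(taus)

  est <- t(vapply(seq_along(q), function(i) {
    hs <- r2s <- numeric(length(tau_max_range))
    for (k in seq_along(tau_max_range)) {
      sel <- taus <= tau_max_range[k]
      fit <- stats::lm.fit(cbind(1, lt[sel]), lk[i, sel])
      slope <- fit$coefficients[2]
      ssr <- sum(fit$residuals^2)
      sst <- sum((lk[i, sel] - mean(lk[i, sel]))^2)
      hs[k] <- slope / q[i]
      r2s[k] <- if (sst > 0) 1 - ssr / sst else 1
    }
    c(mean(hs), mean(r2s))
  }, numeric(2)))

  structure(list(table = data.frame(q = q, hurst = est[, 1],
                                    fit_r2 = est[, 2]),
                 q = q, tau_min = tau_min, tau_max_range = tau_max_range,
                 n = n, estimator = "ghe"),
            class = "ghe_fit")
}

#' Multifractal detrended fluctuation analysis
#'
#' MFDFA with linear detrending: the profile (cumulative sum of the
#' mean-centred series) is cut into non-overlapping segments of each scale
#' `s` (taken from both ends of the series), each segment is detrended by an
#' order-1 polynomial, and the q-order fluctuation function
#' \eqn{F_q(s) = \{\mathrm{mean}_v [F^2(v,s)]^{q/2}\}^{1/q}} is regressed on
#' `s` in log-log coordinates to give the generalized exponent h(q).
#' For stationary (noise-like) input h(2) estimates the Hurst exponent in
#' (0, 1); for already-integrated (walk-scale) input h(2) exceeds 1 by one
#' -- the regime in which reported EEG exponents above unity arise.
#'
#' @param series numeric vector.
#' @param q vector of nonzero moment orders (default 1:5).
#' @param scale_min smallest segment length in samples (default 16).
#' @param scale_max largest segment length (default `length(series)/4`).
#' @param n_scales number of log-spaced scales (default 19).
#' @param fs,decimate_to_hz as in [ghe()].
#' @return Object of class `ghe_fit` with `estimator = "mfdfa"`; `table`
#'   has columns `q`, `hurst` (= h(q)) and `fit_r2`.
#' @export
mfdfa <- function(series, q = 1:5, scale_min = 16L, scale_max = NULL,
                  n_scales = 19L, fs = NULL, decimate_to_hz = NULL) {
  if (!is.null(decimate_to_hz)) {
    if (is.null(fs)) stop("fs required for decimation")
    series <- decimate_series(series, fs, decimate_to_hz)$x
  }
  n <- length(series)
  if (n < 100L) stop("series too short (< 100 samples) for MFDFA")
  if (any(q == 0)) stop("q = 0 is not supported")
  if (stats::sd(series) == 0) stop("degenerate series: zero variance")
  if (is.null(scale_max)) scale_max <- floor(n / 4)
  scales <- unique(round(exp(seq(log(scale_min), log(scale_max),
                                 length.out = n_scales))))
  y <- cumsum(series - mean(series))

  fq <- matrix(NA_real_, length(q), length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    ns <- n %/% s
    # forward and reverse coverage so the tail is not discarded
    seg_f <- matrix(y[seq_len(ns * s)], nrow = s)
    seg_b <- matrix(y[(n - ns * s + 1L):n], nrow = s)
    segs <- cbind(seg_f, seg_b)
    t1 <- seq_len(s) - (s + 1) / 2          # centred time axis
    stt <- sum(t1^2)
    cm <- colMeans(segs)
    slope <- as.vector(crossprod(t1, segs)) / stt
    rss <- colSums(segs^2) - s * cm^2 - slope^2 * stt
    f2 <- pmax(rss / s, .Machine$double.xmin)
    for (i in seq_along(q))
      fq[i, si] <- mean(f2^(q[i] / 2))^(1 / q[i])
  }

  ls <- log(scales)
  est <- t(vapply(seq_along(q), function(i) {
    lf <- log(fq[i, ])
    fit <- stats::lm.fit(cbind(1, ls), lf)
    ssr <- sum(fit$residuals^2)
    sst <- sum((lf - mean(lf))^2)
    c(fit$coefficients[2], if (sst > 0) 1 - ssr / sst else 1)
  }, numeric(2)))

  structure(list(table = data.frame(q = q, hurst = est[, 1],
                                    fit_r2 = est[, 2]),
                 q = q, scales = scales, n = n, estimator = "mfdfa"),
            class = "ghe_fit")
}

#' @export
print.ghe_fit <- function(x, ...) {
  cat(sprintf("<%s fit> n = %d\n",
              if (x$estimator == "ghe") "generalized Hurst exponent"
              else "MFDFA", x$n))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.ghe_fit <- function(object, ...) {
  stats::setNames(object$table$hurst, paste0("H(", object$table$q, ")"))
}

#' @export
summary.ghe_fit <- function(object, ...) {
  h2 <- object$table$hurst[match(2, object$table$q)]
  width <- diff(range(object$table$hurst))
  structure(list(fit = object, h2 = h2, multifractal_width = width,
                 persistence = if (!is.na(h2))
                   classify_persistence(h2)$label else NA_character_),
            class = "summary.ghe_fit")
}

#' @export
print.summary.ghe_fit <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$h2))
    cat(sprintf("H(2) = %.4f (%s); H(q) spread over q: %.4f\n",
                x$h2, x$persistence, x$multifractal_width))
  invisible(x)
}

#' @export
plot.ghe_fit <- function(x, ...) {
  graphics::plot(x$table$q, x$table$hurst, type = "b", pch = 19,
                 xlab = "moment order q", ylab = "H(q)",
                 main = paste(toupper(x$estimator), "generalized exponents"),
                 ...)
  invisible(x)
}

#' Classify a Hurst exponent against the persistence threshold
#'
#' Series with H below the threshold T = 0.5 oscillate around a central
#' value (anti-persistent, short memory); H above T indicates the Hurst
#' effect -- persistent, trend-reinforcing dynamics. Estimates within
#' `tie_band` of T are labelled `"threshold"` rather than forced to a side.
#'
#' @param h finite Hurst estimate.
#' @param threshold_T boundary value (default 0.5).
#' @param tie_band half-width of the indeterminate zone (default 0.01).
#' @return List with `label` (one of `"anti-persistent"`, `"threshold"`,
#'   `"persistent"`), `threshold_T`, `tie_band`.
#' @export
classify_persistence <- function(h, threshold_T = 0.5, tie_band = 0.01) {
  if (!is.finite(h)) stop("h must be finite")
  label <- if (abs(h - threshold_T) <= tie_band) "threshold"
  else if (h < threshold_T) "anti-persistent" else "persistent"
  list(label = label, threshold_T = threshold_T, tie_band = tie_band)
}

#' Shuffle surrogate
#'
#' Uniform random permutation of the samples: the value distribution is
#' preserved exactly while all temporal correlation is destroyed, so any
#' scaling estimate on the surrogate should collapse to the uncorrelated
#' value (h(2) near 0.5 for noise-scale estimators).
#'
#' @param series numeric vector.
#' @param seed integer seed.
#' @return Permuted copy of `series`.
#' @export
shuffle_surrogate <- function(series, seed = 1L) {
  if (length(series) == 0L) stop("series must be non-empty")
  set.seed(as.integer(seed))
  series[sample.int(length(series))]
}

#' Windowed Hurst exponents per channel and band
#'
#' Runs the chosen estimator on every (channel, window, band) cell of a
#' preprocessed recording and returns one row per (cell, q). The
#' full-spectrum band is always included. Cells where estimation fails are
#' flagged (`ok = FALSE`, `hurst = NA`) rather than dropped.
#'
#' @param rec a preprocessed [recording()].
#' @param windows a [window_spec()].
#' @param bands named list of [band_definition()]s to add beyond `full`
#'   (default: none -- full spectrum only).
#' @param q moment orders.
#' @param estimator `"ghe"` or `"mfdfa"`.
#' @param decimate_to_hz target rate before estimation (default 500; set
#'   `NULL` to estimate at the native rate).
#' @param ... passed to [ghe()] or [mfdfa()].
#' @return Data frame with columns `subject_id`, `channel`, `band`,
#'   `window_start_s`, `q`, `hurst`, `fit_r2`, `estimator`, `ok`.
#' @export
windowed_hfd <- function(rec, windows = window_spec(), bands = list(),
                         q = 1:5, estimator = c("ghe", "mfdfa"),
                         decimate_to_hz = 500, ...) {
  stopifnot(inherits(rec, "eeg_recording"))
  estimator <- match.arg(estimator)
  if (!"full" %in% names(bands)) bands <- c(list(full = NULL), bands)
  sid <- if (!is.null(rec$meta)) rec$meta$subject_id else NA_character_

  band_recs <- lapply(names(bands), function(b) {
    if (is.null(bands[[b]]) || b == "full") rec else extract_band(rec, bands[[b]])
  })
  names(band_recs) <- names(bands)

  rows <- list()
  for (b in names(band_recs)) {
    brec <- band_recs[[b]]
    dec <- if (!is.null(decimate_to_hz))
      decimate_series(brec$samples, brec$fs, decimate_to_hz)
    else list(x = brec$samples, fs = brec$fs)
    drec <- brec; drec$samples <- dec$x; drec$fs <- dec$fs
    wins <- segment_windows(drec, windows)
    for (w in wins) {
      for (ch in seq_len(nrow(w$samples))) {
        res <- tryCatch({
          f <- if (estimator == "ghe") ghe(w$samples[ch, ], q = q, ...)
          else mfdfa(w$samples[ch, ], q = q, ...)
          cbind(f$table, ok = TRUE)
        }, error = function(e)
          data.frame(q = q, hurst = NA_real_, fit_r2 = NA_real_, ok = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, channel = w$channel_labels[ch], band = b,
          window_start_s = w$window_start_s, q = res$q, hurst = res$hurst,
          fit_r2 = res$fit_r2, estimator = estimator, ok = res$ok,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
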