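#' Specification of a fractional Gaussian noise series
#'
#' Bundles the parameters of a stationary fractional Gaussian noise (fGn)
#' process: series length, Hurst exponent and marginal standard deviation.
#' fGn is the increment process of fractional Brownian motion; its
#' autocovariance is
#' \deqn{\gamma(k) = \frac{\sigma^2}{2}\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right).}
#'
#' @param n_samples integer, series length (>= 16).
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param sigma marginal standard deviation (> 0).
#' @param seed integer seed; every generator call with the same spec returns
#'   the identical series.
#' @return An object of class `fgn_spec`.
#' @examples
#' sp <- fgn_spec(1024, hurst = 0.7, seed = 1)
#' x <- generate_fgn(sp)
#' @export
fgn_spec <- function(n_samples, hurst, sigma = 1, seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 16L)
    stop("n_samples must be an integer >= 16")
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1)
    stop("hurst must lie strictly inside (0, 1)")
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be positive")
  structure(list(n_samples = n_samples, hurst = hurst,
                 sigma = sigma, seed = as.integer(seed)),
            class = "fgn_spec")
}

# fGn autocovariance gamma(k), k >= 0
fgn_acvf <- function(k, hurst, sigma = 1) {
  h2 <- 2 * hurst
  0.5 * sigma^2 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

#' Generate fractional Gaussian noise by exact circulant embedding
#'
#' Davies-Harte construction: the autocovariance sequence is embedded in a
#' circulant matrix whose eigenvalues are obtained by FFT; a complex Gaussian
#' vector shaped by the square-rooted eigenvalues is transformed back, giving
#' a sample with *exactly* the fGn autocovariance (no approximation). For
#' Hurst exponents in (0, 1) the embedding is provably non-negative definite;
#' a negative eigenvalue therefore signals an implementation bug and raises
#' an error rather than being truncated.
#'
#' @param spec an [fgn_spec()].
#' @return Numeric vector of length `spec$n_samples`.
#' @seealso [generate_fbm_path()] for the integrated (path-scale) series.
#' @export
generate_fgn <- function(spec) {
  stopifnot(inherits(spec, "fgn_spec"))
  n <- spec$n_samples
  m <- 2L * n
  g <- fgn_acvf(0:n, spec$hurst, spec$sigma)
  # first row of the 2n x 2n circulant: g0..gn, g(n-1)..g1
  row <- c(g, g[n:2])
  lambda <- Re(stats::fft(row))
  if (any(lambda < -1e-8 * max(lambda)))
    stop("circulant embedding produced negative eigenvalues; ",
         "this should be impossible for H in (0,1) and indicates a bug")
  lambda[lambda < 0] <- 0

  set.seed(spec$seed)
  u <- stats::rnorm(m)
  v <- stats::rnorm(m)
  w <- complex(length.out = m)
  half <- n  # m/2
  w[1] <- sqrt(lambda[1]) * u[1]
  w[half + 1] <- sqrt(lambda[half + 1]) * u[half + 1]
  idx <- 2:half
  w[idx] <- sqrt(lambda[idx] / 2) * complex(real = u[idx], imaginary = v[idx])
  w[m + 2 - idx] <- Conj(w[idx])
  x <- Re(stats::fft(w)) / sqrt(m)
  x[seq_len(n)]
}

#' Generate a fractional Brownian motion path
#'
#' Cumulative sum of [generate_fgn()]. The resulting path is self-similar
#' with path-scale Hurst exponent `spec$hurst`: its q-order structure
#' functions scale as \eqn{K_q(\tau) \propto \tau^{qH}}. With `hurst = 0.5`
#' the path is an ordinary Gaussian random walk.
#'
#' @inheritParams generate_fgn
#' @return Numeric vector of length `spec$n_samples`.
#' @export
generate_fbm_path <- function(spec) {
  cumsum(generate_fgn(spec))
}

#' Generate a multiplicative binomial cascade measure
#'
#' Builds the classical multifractal binomial measure on `2^n_levels` dyadic
#' cells: mass is split recursively, a fraction `weight_p` to one half and
#' `1 - weight_p` to the other, the side receiving the larger share chosen
#' at random at every split. The cumulative mass path of the measure has
#' multifractal scaling with partition-function exponents
#' \eqn{\tau(q) = -\log_2(p^q + (1-p)^q)}, so the generalized Hurst exponent
#' \eqn{H(q) = (\tau(q) + 1)/q} decreases strictly in q for `weight_p > 0.5`
#' -- a standard positive control for multifractality detectors.
#'
#' @param n_levels integer >= 4; series length is `2^n_levels`.
#' @param weight_p mass fraction in (0.5, 1); values near 0.5 give a nearly
#'   uniform (monofractal) measure.
#' @param seed integer seed.
#' @return Numeric vector of length `2^n_levels` (the cell masses, summing
#'   to 1).
#' @export
generate_binomial_cascade <- function(n_levels, weight_p = 0.7, seed = 1L) {
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 4L) stop("n_levels must be >= 4")
  if (!is.numeric(weight_p) || weight_p <= 0.5 || weight_p >= 1)
    stop("weight_p must lie in (0.5, 1)")
  set.seed(as.integer(seed))
  mass <- 1
  for (lev in seq_len(n_levels)) {
    flip <- stats::runif(length(mass)) < 0.5
    left <- ifelse(flip, weight_p, 1 - weight_p)
    mass <- as.vector(rbind(mass * left, mass * (1 - left)))
  }
  mass
}

#' Analytic scaling exponents of the binomial cascade
#'
#' Closed form \eqn{\tau(q) = -\log_2(p^q + (1-p)^q)} for the cascade built
#' by [generate_binomial_cascade()]; the generalized Hurst exponent of the
#' cumulative mass path is \eqn{H(q) = (\tau(q)+1)/q}.
#'
#' @param q vector of positive moment orders.
#' @param weight_p cascade weight in (0.5, 1).
#' @return Data frame with columns `q`, `tau_q`, `H_q`.
#' @export
cascade_scaling_exponents <- function(q, weight_p) {
  tau <- -log2(weight_p^q + (1 - weight_p)^q)
  data.frame(q = q, tau_q = tau, H_q = (tau + 1) / q)
}
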