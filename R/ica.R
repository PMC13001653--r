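# FastICA (deflation scheme) with the tanh (logcosh) contrast. Data are
# centred and whitened by PCA; each unmixing row is found by the standard
# fixed-point iteration with Gram-Schmidt orthogonalization against the
# rows already extracted. Convergence is tracked per component: strongly
# non-Gaussian sources (e.g. blink transients) converge in a few tens of
# iterations, while directions spanning a Gaussian subspace have no
# preferred rotation and may exhaust `max_iter` -- they are returned with
# `component_converged = FALSE` and are still a valid orthonormal basis of
# the residual subspace. Deterministic under `seed`.
fastica_decompose <- function(x, n_components = nrow(x), max_iter = 200L,
                              tol = 1e-6, seed = 1L) {
  nch <- nrow(x)
  n <- ncol(x)
  if (n_components > nch) stop("n_components must be <= number of channels")
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  K <- diag(1 / sqrt(pmax(eg$values[keep], 1e-12))) %*%
    t(eg$vectors[, keep, drop = FALSE])
  z <- K %*% xc  # whitened, n_components x n

  set.seed(as.integer(seed))
  W <- matrix(0, n_components, n_components)
  comp_ok <- logical(n_components)
  iters <- integer(n_components)
  for (i in seq_len(n_components)) {
    w <- stats::rnorm(n_components)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wz <- drop(crossprod(w, z))
      g <- tanh(wz)
      w1 <- z %*% g / n - mean(1 - g^2) * w
      if (i > 1) {
        prev <- W[seq_len(i - 1), , drop = FALSE]
        w1 <- w1 - t(prev) %*% (prev %*% w1)
      }
      w1 <- w1 / sqrt(sum(w1^2))
      delta <- abs(abs(sum(w1 * w)) - 1)
      w <- drop(w1)
      if (delta < tol) { comp_ok[i] <- TRUE; break }
    }
    iters[i] <- it
    W[i, ] <- w
  }
  unmixing <- W %*% K                       # sources = unmixing %*% (x - mu)
  mixing <- MASS_ginv(unmixing)             # x ~ mixing %*% sources + mu
  list(sources = unmixing %*% xc, unmixing = unmixing, mixing = mixing,
       center = mu, converged = any(comp_ok), component_converged = comp_ok,
       iterations = iters)
}

# Moore-Penrose pseudoinverse (small matrices only)
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

sample_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2
}

#' Remove ocular components by FastICA
#'
#' Decomposes the recording into independent components and automatically
#' rejects those that look ocular: the component's scalp pattern (mixing
#' column) must correlate with a frontal template above
#' `template_threshold`, and its time course must be super-Gaussian
#' (kurtosis above `kurtosis_threshold` -- blinks are sparse transients).
#' Rejected components are zeroed and the mixing applied back. This is an
#' automated, reproducible stand-in for visual inspection of component
#' topography and time course.
#'
#' When `apply_to` is supplied, the unmixing learned on `rec` (typically
#' the 1-45 Hz filtered data) is applied to that second recording (e.g. the
#' wider-band, drift/line-cleaned data) and the same components are removed
#' there -- the usual two-pass scheme.
#'
#' @param rec an [recording()] (with montage) on which ICA is learned.
#' @param n_components number of components (default: number of channels).
#' @param eog_template named weight vector over channels (default:
#'   [eog_template()] of the recording montage).
#' @param template_threshold minimum |correlation| between a component's
#'   scalp map and the template (default 0.7).
#' @param kurtosis_threshold minimum time-course kurtosis (default 5).
#' @param apply_to optional second recording to clean with the learned
#'   unmixing.
#' @param seed seed for the FastICA initialisation.
#' @param max_iter FastICA iteration cap; on non-convergence the input is
#'   returned unchanged with a warning and `report$converged = FALSE`.
#' @return List with `recording` (cleaned), `report` (rejected component
#'   indices, template correlations, kurtoses, convergence flag).
#' @export
remove_ocular_ica <- function(rec, n_components = NULL, eog_template = NULL,
                              template_threshold = 0.7,
                              kurtosis_threshold = 5,
                              apply_to = NULL, seed = 1L, max_iter = 200L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nch <- nrow(rec$samples)
  if (is.null(n_components)) n_components <- nch
  if (n_components > nch) stop("n_components must be <= channel count")
  if (is.null(eog_template)) {
    if (is.null(rec$montage)) stop("need a montage or an explicit template")
    eog_template <- eog_template(rec$montage)
  }
  tmpl <- eog_template[rec$channel_labels]
  if (anyNA(tmpl)) stop("template does not cover all channels")

  dec <- fastica_decompose(rec$samples, n_components, max_iter = max_iter,
                           seed = seed)
  if (!dec$converged) {
    warning("FastICA did not converge; recording passed through unchanged")
    rep0 <- list(rejected = integer(0), template_correlation = numeric(0),
                 kurtosis = numeric(0), converged = FALSE)
    return(list(recording = add_provenance(rec, "remove_ocular_ica",
                                           list(converged = FALSE)),
                report = rep0))
  }

  maps <- dec$mixing  # nch x n_components scalp patterns
  tc <- apply(maps, 2L, function(m) abs(stats::cor(m, tmpl)))
  ku <- apply(dec$sources, 1L, sample_kurtosis)
  # only individually converged components are candidates for rejection
  rejected <- which(tc >= template_threshold & ku >= kurtosis_threshold &
                      dec$component_converged)

  clean_with <- function(target) {
    ctr <- rowMeans(target$samples)
    src <- dec$unmixing %*% (target$samples - ctr)
    src[rejected, ] <- 0
    out <- target
    out$samples <- dec$mixing %*% src + ctr
    rownames(out$samples) <- target$channel_labels
    add_provenance(out, "remove_ocular_ica",
                   list(n_components = n_components, rejected = rejected,
                        template_threshold = template_threshold,
                        kurtosis_threshold = kurtosis_threshold, seed = seed))
  }
  target <- if (is.null(apply_to)) rec else apply_to
  list(recording = clean_with(target),
       report = list(rejected = rejected, template_correlation = tc,
                     kurtosis = ku, converged = TRUE,
                     iterations = dec$iterations))
}
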