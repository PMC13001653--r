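#' Extended 10-20 montage for 63 analysis channels
#'
#' Returns a schematic 2-D layout of 63 scalp electrodes named after the
#' extended international 10-20 (10-10) system, on the unit disc viewed from
#' above (nose up: +y anterior, +x right). The coordinates are a standard
#' schematic projection intended for topographic interpolation, frontal
#' weighting templates and region assignment -- not a digitized head model.
#'
#' @param n_channels number of channels; only the default 63 and prefixes of
#'   it (the first `n_channels` electrodes in anterior-to-posterior order)
#'   are supported.
#' @return Data frame with columns `label`, `x`, `y`, `region`.
#' @export
montage_1020 <- function(n_channels = 63L) {
  rows <- list(
    list(y = 0.95, labels = c("Fp1", "Fpz", "Fp2")),
    list(y = 0.76, labels = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y = 0.57, labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    list(y = 0.29, labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8")),
    list(y = 0.00, labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    list(y = -0.29, labels = c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2",
                               "CP4", "CP6", "TP8", "TP10")),
    list(y = -0.57, labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
    list(y = -0.76, labels = c("PO7", "PO3", "POz", "PO4", "PO8")),
    list(y = -0.95, labels = c("O1", "Oz", "O2"))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    k <- length(r$labels)
    half <- sqrt(max(1 - r$y^2, 0.05))
    x <- if (k == 1) 0 else seq(-half, half, length.out = k)
    data.frame(label = r$labels, x = x, y = r$y, stringsAsFactors = FALSE)
  }))
  if (n_channels > nrow(out))
    stop("montage supports at most ", nrow(out), " channels")
  out <- out[seq_len(n_channels), , drop = FALSE]
  out$region <- scalp_region(out$label)
  rownames(out) <- NULL
  out
}

#' Coarse scalp region from a 10-20 electrode label
#'
#' Maps extended 10-20 labels onto five conventional scalp regions
#' (frontal, central, temporal, parietal, occipital) by their letter prefix.
#' Used to coarsen the 63-level electrode factor for factorial statistics.
#'
#' @param labels character vector of electrode labels.
#' @return Character vector of region names.
#' @export
scalp_region <- function(labels) {
  prefix <- sub("[0-9z]+$", "", labels)
  map <- c(Fp = "frontal", AF = "frontal", F = "frontal",
           FT = "temporal", FC = "central", T = "temporal", C = "central",
           TP = "temporal", CP = "parietal", P = "parietal",
           PO = "occipital", O = "occipital")
  out <- unname(map[prefix])
  if (anyNA(out))
    stop("unrecognised electrode label(s): ",
         paste(labels[is.na(out)], collapse = ", "))
  out
}

#' Frontal (ocular) scalp weighting template
#'
#' A per-electrode weight vector peaking at the prefrontal midline, modelling
#' the scalp projection of ocular sources (blinks load mostly on Fp/AF
#' electrodes). Weights are `exp(-d^2 / 0.18)` where `d` is the distance to
#' the point just above Fpz, normalized to unit maximum.
#'
#' @param montage montage data frame as from [montage_1020()].
#' @return Named numeric vector of weights in (0, 1], one per electrode.
#' @export
eog_template <- function(montage) {
  d2 <- montage$x^2 + (montage$y - 1.05)^2
  w <- exp(-d2 / 0.18)
  stats::setNames(w / max(w), montage$label)
}
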