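#' Multichannel EEG recording container
#'
#' Lightweight container for a continuous multichannel recording: a channels
#' x time numeric matrix in microvolts, the sampling rate, channel labels, a
#' 2-D montage and subject metadata. Every processing step appends an entry
#' to the `provenance` list (step name plus parameters), so a processed
#' recording carries its own history.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling frequency in Hz.
#' @param channel_labels character vector, one unique label per row of
#'   `samples`.
#' @param montage data frame with columns `label`, `x`, `y` covering all
#'   channels (see [montage_1020()]); may be `NULL` for label-free use.
#' @param meta a [subject_meta()] row or `NULL`.
#' @param provenance list of processing-step records (internal use).
#' @return Object of class `eeg_recording`.
#' @export
recording <- function(samples, fs, channel_labels = rownames(samples),
                      montage = NULL, meta = NULL, provenance = list()) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(channel_labels))
    channel_labels <- paste0("Ch", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples))
    stop("one label per channel required")
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (!is.null(montage) && !all(channel_labels %in% montage$label))
    stop("montage does not cover all channels")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 montage = montage, meta = meta, provenance = provenance),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$fs
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.6g Hz, %.6g s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, dur))
  if (!is.null(x$meta))
    cat(sprintf("  subject %s  group %s  sex %s  handedness %s  age %s\n",
                x$meta$subject_id, x$meta$group, x$meta$sex,
                x$meta$handedness, x$meta$age))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return Numeric scalar.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

# append a provenance entry, returning the recording
add_provenance <- function(rec, step, params = list()) {
  rec$provenance <- c(rec$provenance, list(list(step = step, params = params)))
  rec
}
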