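#' Read a multichannel EEG recording from disk
#'
#' Dispatches on format: the BrainVision triplet (`.vhdr` INI-style header,
#' `.vmrk` markers, `.eeg` int16 multiplexed binary) or European Data Format
#' (EDF). Samples are returned in microvolts with channels in header order.
#'
#' @param path path to the `.vhdr` (BrainVision) or `.edf` file.
#' @param format `"brainvision"` or `"edf"`; guessed from the extension when
#'   missing.
#' @param montage optional montage to attach (see [montage_1020()]).
#' @return An [recording()].
#' @export
read_recording <- function(path, format = c("auto", "brainvision", "edf"),
                           montage = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vhdr = "brainvision", edf = "edf",
                     stop("cannot guess format from extension '.", ext, "'"))
  }
  switch(format,
         brainvision = read_brainvision(path, montage),
         edf = read_edf(path, montage))
}

# --- BrainVision -----------------------------------------------------------

parse_vhdr <- function(lines) {
  section <- ""
  kv <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      kv[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      key <- sub("=.*$", "", ln)
      val <- sub("^[^=]*=", "", ln)
      kv[[section]][[key]] <- val
    }
  }
  kv
}

#' Read a BrainVision recording
#'
#' Supports the common layout: binary multiplexed little-endian `INT_16`
#' data with a per-channel resolution (uV/bit) in the header. The `.vmrk`
#' and `.eeg` siblings named in the header must sit next to the `.vhdr`.
#' Distinct errors are raised for a missing sibling file, a header/payload
#' length mismatch, and unsupported encodings.
#'
#' @param vhdr_path path to the `.vhdr` header.
#' @param montage optional montage to attach.
#' @return An [recording()].
#' @export
read_brainvision <- function(vhdr_path, montage = NULL) {
  if (!file.exists(vhdr_path)) stop("header file not found: ", vhdr_path)
  hdr <- parse_vhdr(readLines(vhdr_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: missing [Common Infos]")
  if (!identical(toupper(ci$DataFormat), "BINARY"))
    stop("unsupported BrainVision DataFormat: ", ci$DataFormat)
  if (!identical(toupper(ci$DataOrientation), "MULTIPLEXED"))
    stop("unsupported DataOrientation: ", ci$DataOrientation)
  fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat)
  if (!identical(fmt, "INT_16"))
    stop("unsupported BinaryFormat: ", fmt)
  nch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)  # interval is in microseconds

  dir <- dirname(vhdr_path)
  data_path <- file.path(dir, ci$DataFile)
  if (!file.exists(data_path))
    stop("missing BrainVision data sibling: ", ci$DataFile)
  if (!is.null(ci$MarkerFile) && !file.exists(file.path(dir, ci$MarkerFile)))
    stop("missing BrainVision marker sibling: ", ci$MarkerFile)

  chinfo <- hdr[["Channel Infos"]]
  labels <- character(nch); res <- numeric(nch)
  for (i in seq_len(nch)) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    res[i] <- if (length(parts) >= 3 && nzchar(parts[3]))
      as.numeric(parts[3]) else 1
  }

  n_bytes <- file.size(data_path)
  if (n_bytes %% (2L * nch) != 0)
    stop("header/data length mismatch: payload of ", n_bytes,
         " bytes is not a whole number of ", nch, "-channel int16 frames")
  n_samp <- n_bytes / (2L * nch)
  raw <- readBin(data_path, what = "integer", n = nch * n_samp,
                 size = 2L, signed = TRUE, endian = "little")
  x <- matrix(as.numeric(raw), nrow = nch) * res
  recording(x, fs, labels, montage = montage,
            provenance = list(list(step = "read_brainvision",
                                   params = list(path = vhdr_path))))
}

#' Write a recording as a BrainVision triplet
#'
#' Emits `.vhdr`, `.vmrk` and `.eeg` files: 16-bit little-endian multiplexed
#' binary with a per-channel resolution chosen so the full signal range maps
#' onto the int16 range (quantization error <= resolution/2).
#'
#' @param rec an [recording()].
#' @param base_path output path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, base_path) {
  stopifnot(inherits(rec, "eeg_recording"))
  nch <- nrow(rec$samples)
  stem <- basename(base_path)
  vhdr <- paste0(base_path, ".vhdr")
  vmrk <- paste0(base_path, ".vmrk")
  eeg <- paste0(base_path, ".eeg")

  amax <- apply(abs(rec$samples), 1L, max)
  res <- pmax(amax / 32000, 1e-6)  # uV per bit
  q <- round(sweep(rec$samples, 1L, res, "/"))
  q[q > 32767] <- 32767; q[q < -32768] <- -32768

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%.10g,µV", seq_len(nch), rec$channel_labels, res)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]",
               paste0("DataFile=", stem, ".eeg"),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,0"), vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  invisible(vhdr)
}

# --- EDF -------------------------------------------------------------------

pad_ascii <- function(x, width) {
  s <- substr(format(x, scientific = FALSE, trim = TRUE), 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' Minimal continuous-EDF writer: one data record per second (so `fs` must
#' be a whole number), int16 samples, physical range chosen per channel to
#' cover the signal.
#'
#' @param rec an [recording()].
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  nch <- nrow(rec$samples)
  n <- ncol(rec$samples)
  n_rec <- n %/% fs
  if (n_rec * fs != n)
    stop("EDF writer requires a whole number of 1 s records")

  pmax_ <- apply(abs(rec$samples), 1L, max)
  pmax_ <- pmax(ceiling(pmax_) + 1, 1)
  dmin <- -32768L; dmax <- 32767L

  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii("X X X X", 80),
    pad_ascii(if (!is.null(rec$meta)) rec$meta$subject_id else "synthetic", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256L * (nch + 1L), 8),
    pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(1, 8), pad_ascii(nch, 4),
    paste0(pad_ascii(rec$channel_labels, 16), collapse = ""),
    paste0(rep(pad_ascii("AgAgCl electrode", 80), nch), collapse = ""),
    paste0(rep(pad_ascii("uV", 8), nch), collapse = ""),
    paste0(pad_ascii(-pmax_, 8), collapse = ""),
    paste0(pad_ascii(pmax_, 8), collapse = ""),
    paste0(rep(pad_ascii(dmin, 8), nch), collapse = ""),
    paste0(rep(pad_ascii(dmax, 8), nch), collapse = ""),
    paste0(rep(pad_ascii("", 80), nch), collapse = ""),
    paste0(rep(pad_ascii(fs, 8), nch), collapse = ""),
    paste0(rep(pad_ascii("", 32), nch), collapse = "")
  )
  stopifnot(nchar(hdr) == 256L * (nch + 1L))

  scale <- (2 * pmax_) / (dmax - dmin)  # uV per digital unit
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    phys <- rec$samples[, idx, drop = FALSE]
    blk <- round(sweep(sweep(phys, 1L, -pmax_), 1L, scale, "/")) + dmin
    blk[blk > dmax] <- dmax; blk[blk < dmin] <- dmin
    writeBin(as.integer(t(blk)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Continuous EDF with a common sampling rate across channels. Raises a
#' length-mismatch error when the payload is shorter than the header
#' promises.
#'
#' @param path `.edf` path.
#' @param montage optional montage to attach.
#' @return An [recording()].
#' @export
read_edf <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  units <- vapply(seq_len(nch), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: channels with differing sampling rates")
  fs <- spr[1] / rec_dur

  expected <- 2 * sum(spr) * n_rec
  payload <- file.size(path) - hdr_bytes
  if (payload < expected)
    stop("header/data length mismatch: EDF payload has ", payload,
         " bytes, header promises ", expected)

  scale <- (pmax_ - pmin) / (dmax - dmin)
  x <- matrix(0, nch, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = sum(spr), size = 2L,
                   signed = TRUE, endian = "little")
    blk <- matrix(as.numeric(raw), nrow = spr[1])  # samples x channels
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    phys <- sweep(sweep(blk, 2L, dmin, "-"), 2L, scale, "*")
    x[, idx] <- t(sweep(phys, 2L, pmin, "+"))
  }
  recording(x, fs, labels, montage = montage,
            provenance = list(list(step = "read_edf",
                                   params = list(path = path))))
}
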