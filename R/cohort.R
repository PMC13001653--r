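#' Subject metadata record
#'
#' One row of the study roster: subject identifier, group (`C` healthy
#' control, `N` chronic pain without opioid medication, `O` chronic pain on
#' opioid medication), sex, handedness and age.
#'
#' @param subject_id character id, unique within a cohort.
#' @param group one of `"C"`, `"N"`, `"O"`.
#' @param sex one of `"M"`, `"F"`.
#' @param handedness one of `"R"`, `"L"`.
#' @param age age in years.
#' @return One-row data frame of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, group, sex, handedness, age) {
  group <- match.arg(group, c("C", "N", "O"))
  sex <- match.arg(sex, c("M", "F"))
  handedness <- match.arg(handedness, c("R", "L"))
  structure(data.frame(subject_id = subject_id, group = group, sex = sex,
                       handedness = handedness, age = as.numeric(age),
                       stringsAsFactors = FALSE),
            class = c("subject_meta", "data.frame"))
}

#' Default study roster
#'
#' The default 23-subject roster used by the synthetic cohort generator:
#' 9 healthy controls (C1-C9), 5 chronic-pain subjects not taking opioids
#' (N1-N5) and 9 chronic-pain subjects on opioid medication (O1-O9), with
#' the corresponding sexes, handedness (one left-handed control, three
#' left-handed opioid subjects) and ages.
#'
#' @return Data frame with columns `subject_id`, `group`, `sex`,
#'   `handedness`, `age`.
#' @export
default_roster <- function() {
  data.frame(
    subject_id = c(paste0("C", 1:9), paste0("N", 1:5), paste0("O", 1:9)),
    group = rep(c("C", "N", "O"), c(9L, 5L, 9L)),
    sex = c("F", "F", "F", "F", "M", "M", "F", "M", "F",
            "M", "F", "F", "F", "M",
            "F", "M", "F", "F", "F", "F", "F", "M", "F"),
    handedness = c("R", "R", "R", "R", "R", "R", "L", "R", "R",
                   "R", "R", "R", "R", "R",
                   "R", "R", "R", "R", "L", "L", "L", "R", "R"),
    age = c(59, 61, 60, 52, 36, 25, 29, 28, 32,
            73, 66, 55, 92, 39,
            58, 75, 47, 39, 70, 74, 64, 47, 47),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic EEG cohort
#'
#' Describes a cohort of synthetic resting-state recordings: the subject
#' roster, the target path-scale Hurst exponent per group, the recording
#' geometry and which stereotyped artifacts to inject. Defaults mirror the
#' acquisition geometry the pipeline targets: 63 channels at 5000 Hz for
#' 180 s. Group Hurst targets are free parameters of the simulation -- the
#' generator makes no claim about what real cohorts look like; defaults
#' place the no-opioid group slightly below the other two so that a
#' configured group effect exists for the statistical battery to recover.
#'
#' @param subjects roster data frame (see [default_roster()]).
#' @param group_hurst named numeric vector mapping group labels to target
#'   walk-scale Hurst exponents in (0, 1).
#' @param n_channels number of channels (<= 63).
#' @param fs sampling frequency, Hz.
#' @param duration_s recording length, seconds; `fs * duration_s` must be a
#'   whole number of samples.
#' @param line_noise,drift,ocular logical artifact flags: 60 Hz mains
#'   sinusoid, sub-0.2 Hz drift, blink transients on frontal channels.
#' @param band_gains named vector of relative amplitudes for oscillatory
#'   band content added on top of the fractal carrier (fraction of carrier
#'   SD); bands whose centre frequency exceeds Nyquist are skipped.
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(subjects = default_roster(),
                        group_hurst = c(C = 0.70, N = 0.55, O = 0.72),
                        n_channels = 63L, fs = 5000, duration_s = 180,
                        line_noise = TRUE, drift = TRUE, ocular = TRUE,
                        band_gains = c(delta = 0.06, theta = 0.05,
                                       alpha = 0.08, beta = 0.04,
                                       gamma = 0.03),
                        seed = 1L) {
  if (nrow(subjects) == 0L) stop("subject list must be non-empty")
  if (anyDuplicated(subjects$subject_id)) stop("subject ids must be unique")
  bad <- setdiff(unique(subjects$group), c("C", "N", "O"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  miss <- setdiff(unique(subjects$group), names(group_hurst))
  if (length(miss)) stop("group_hurst missing label(s): ",
                         paste(miss, collapse = ", "))
  n_total <- fs * duration_s
  if (abs(n_total - round(n_total)) > 1e-9)
    stop("duration_s * fs must be an integer sample count")
  structure(list(subjects = subjects, group_hurst = group_hurst,
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s,
                 line_noise = isTRUE(line_noise), drift = isTRUE(drift),
                 ocular = isTRUE(ocular), band_gains = band_gains,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# raised-cosine blink kernel, 400 ms wide
blink_kernel <- function(fs, width_s = 0.4) {
  n <- max(3L, round(width_s * fs))
  0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
}

#' Generate one synthetic resting-state recording
#'
#' Each channel is an independent fractional Brownian motion path whose
#' path-scale Hurst exponent is the subject's group target, scaled to a
#' 10 uV (SD) carrier. Optional components are added on top: narrow-band
#' oscillations (one randomly phased sinusoid per physiological band, with
#' slow amplitude modulation), a 60 Hz mains sinusoid, a slow (< 0.2 Hz)
#' drift, and blink transients -- 400 ms raised-cosine deflections with
#' Poisson arrivals at 0.2 events/s, 10x the carrier SD, projected onto the
#' scalp through the frontal template of [eog_template()] so that ICA sees
#' a single spatially coherent ocular component.
#'
#' @param cohort a [cohort_spec()].
#' @param subject one row of `cohort$subjects` (data frame or list with the
#'   `subject_meta` fields).
#' @return An [recording()] with montage and metadata attached.
#' @export
generate_recording <- function(cohort, subject) {
  stopifnot(inherits(cohort, "cohort_spec"))
  grp <- as.character(subject$group)
  if (!grp %in% names(cohort$group_hurst))
    stop("unknown group label: ", grp)
  h <- cohort$group_hurst[[grp]]
  fs <- cohort$fs
  n <- as.integer(round(fs * cohort$duration_s))
  nch <- cohort$n_channels
  mont <- montage_1020(nch)
  sub_i <- match(subject$subject_id, cohort$subjects$subject_id)
  if (is.na(sub_i)) sub_i <- 0L
  base_seed <- (cohort$seed * 1009L + sub_i * 131L) %% .Machine$integer.max

  carrier_sd <- 10  # uV
  x <- matrix(0, nch, n)
  inc_sd <- numeric(nch)  # increment scale in the estimator fit range
  for (ch in seq_len(nch)) {
    sp <- fgn_spec(n, hurst = h, sigma = 1,
                   seed = (base_seed + ch) %% .Machine$integer.max)
    path <- generate_fbm_path(sp)
    x[ch, ] <- path * (carrier_sd / stats::sd(path))
    inc_sd[ch] <- stats::sd(diff(x[ch, ], lag = 10L))
  }

  set.seed((base_seed + 7919L) %% .Machine$integer.max)
  t <- seq(0, by = 1 / fs, length.out = n)
  bands <- eeg_bands()
  for (b in names(cohort$band_gains)) {
    bd <- bands[[b]]
    if (is.null(bd) || bd$low_hz >= 0.45 * fs) next
    f0 <- stats::runif(nch, bd$low_hz, min(bd$high_hz, 0.45 * fs))
    # anchor oscillation amplitudes to the carrier's increment scale so the
    # band content shapes the spectrum without destroying the small-lag
    # scaling that the Hurst estimators fit
    amp <- cohort$band_gains[[b]] * inc_sd
    fm <- stats::runif(nch, 0.05, 0.15)  # slow amplitude modulation
    ph <- stats::runif(nch, 0, 2 * pi)
    ph2 <- stats::runif(nch, 0, 2 * pi)
    for (ch in seq_len(nch))
      x[ch, ] <- x[ch, ] + amp[ch] *
        (1 + 0.5 * sin(2 * pi * fm[ch] * t + ph2[ch])) *
        sin(2 * pi * f0[ch] * t + ph[ch])
  }

  if (cohort$line_noise && 60 < fs / 2) {
    ph <- stats::runif(nch, 0, 2 * pi)
    for (ch in seq_len(nch))
      x[ch, ] <- x[ch, ] + 5 * sin(2 * pi * 60 * t + ph[ch])
  }
  if (cohort$drift) {
    f_dr <- stats::runif(nch, 0.02, 0.1)
    ph <- stats::runif(nch, 0, 2 * pi)
    for (ch in seq_len(nch))
      x[ch, ] <- x[ch, ] + 40 * sin(2 * pi * f_dr[ch] * t + ph[ch])
  }
  if (cohort$ocular) {
    rate <- 0.2  # blinks per second
    n_blinks <- stats::rpois(1, rate * cohort$duration_s)
    if (n_blinks > 0) {
      kern <- blink_kernel(fs)
      onset <- sort(stats::runif(n_blinks, 0, cohort$duration_s - 0.4))
      blink <- numeric(n)
      for (o in onset) {
        i0 <- floor(o * fs) + 1L
        ii <- i0:min(i0 + length(kern) - 1L, n)
        blink[ii] <- blink[ii] + kern[seq_along(ii)]
      }
      w <- eog_template(mont)
      x <- x + (10 * carrier_sd) * outer(unname(w), blink)
    }
  }

  meta <- subject_meta(subject$subject_id, grp, as.character(subject$sex),
                       as.character(subject$handedness), subject$age)
  rec <- recording(x, fs, mont$label, montage = mont, meta = meta)
  add_provenance(rec, "simulate",
                 list(group = grp, target_hurst = h, seed = base_seed,
                      line_noise = cohort$line_noise, drift = cohort$drift,
                      ocular = cohort$ocular))
}

#' Generate a full synthetic cohort
#'
#' One recording per roster row, deterministic under the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @return Named list of [recording()] objects (names = subject ids).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- lapply(seq_len(nrow(spec$subjects)), function(i)
    generate_recording(spec, spec$subjects[i, ]))
  stats::setNames(recs, spec$subjects$subject_id)
}

#' Write cohort metadata to CSV
#'
#' Columns: `subject_id`, `group`, `sex`, `handedness`, `age`.
#'
#' @param subjects roster data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(subjects, path) {
  utils::write.csv(subjects[, c("subject_id", "group", "sex",
                                "handedness", "age")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort metadata from CSV
#' @param path CSV path written by [write_cohort_csv()].
#' @return Roster data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "sex", "handedness", "age")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}
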