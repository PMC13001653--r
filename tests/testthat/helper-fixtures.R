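# Shared fixtures: everything is generated in code at test time.

# single- or multi-channel sinusoid recording
sine_recording <- function(freq, fs = 200, dur = 30, n_ch = 1, amp = 1) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  x <- matrix(rep(amp * sin(2 * pi * freq * t), n_ch), n_ch, byrow = TRUE)
  recording(x, fs, paste0("Ch", seq_len(n_ch)))
}

# interior sample range (filter edge transients excluded)
interior <- function(rec, margin_s = 5) {
  n <- ncol(rec$samples)
  m <- round(margin_s * rec$fs)
  (m + 1):(n - m)
}

# small analysis table shaped like windowed_hfd + metadata output
make_hfd_table <- function(n_per_cell = 3, groups = c("C", "N", "O"),
                           group_means = c(C = 0.7, N = 0.55, O = 0.72),
                           sd = 0.02, bands = "full",
                           channels = c("Fp1", "Cz", "O1"), seed = 42) {
  set.seed(seed)
  rows <- expand.grid(group = groups, band = bands, channel = channels,
                      window_start_s = seq(0, by = 30,
                                           length.out = n_per_cell),
                      stringsAsFactors = FALSE)
  rows$subject_id <- paste0(rows$group, "1")
  rows$q <- 2
  rows$hurst <- rnorm(nrow(rows), group_means[rows$group], sd)
  rows$fit_r2 <- 0.99
  rows$sex <- ifelse(rows$group == "N", "M", "F")
  rows$handedness <- ifelse(rows$group == "O", "L", "R")
  rows$region <- scalp_region(rows$channel)
  rows$alpha_excluded <- rows$band == "alpha"
  class(rows) <- c("hfd_table", "data.frame")
  rows
}
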