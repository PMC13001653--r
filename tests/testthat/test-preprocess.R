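test_that("conditioning chain removes mains, drift and DC, keeps passband", {
  fs <- 200
  rec60 <- sine_recording(60, fs = fs)
  out60 <- apply_filters(rec60)
  mid <- interior(rec60)
  expect_lt(sd(out60$samples[1, mid]) / sd(rec60$samples[1, mid]), 0.01)

  rec10 <- sine_recording(10, fs = fs)
  out10 <- apply_filters(rec10)
  expect_equal(sd(out10$samples[1, mid]) / sd(rec10$samples[1, mid]), 1,
               tolerance = 0.01)

  dc <- recording(matrix(5, 1, fs * 30), fs, "A")
  expect_lt(max(abs(apply_filters(dc)$samples)), 0.05)

  t <- seq(1 / fs, 30, by = 1 / fs)
  drift <- recording(matrix(40 * sin(2 * pi * 0.05 * t), 1), fs, "A")
  expect_lt(sd(apply_filters(drift)$samples[1, mid]), 0.4)
})

test_that("filter chain preserves shape, labels and provenance", {
  set.seed(4)
  rec <- recording(matrix(rnorm(3 * 6000), 3), 200, c("Fp1", "Cz", "O1"))
  out <- apply_filters(rec)
  expect_equal(dim(out$samples), dim(rec$samples))
  expect_equal(out$channel_labels, rec$channel_labels)
  expect_equal(out$fs, rec$fs)
  steps <- vapply(out$provenance, `[[`, "", "step")
  expect_true("apply_filters" %in% steps)
  expect_error(apply_filters(rec, band_high = 150), "Nyquist")
})

test_that("filtering is idempotent to within passband ripple", {
  rec <- sine_recording(10, fs = 200)
  once <- apply_filters(rec)
  twice <- apply_filters(once)
  mid <- interior(rec)
  rel <- sd(twice$samples[1, mid] - once$samples[1, mid]) /
    sd(once$samples[1, mid])
  expect_lt(rel, 0.04)
})

test_that("average reference zeroes column sums and is idempotent", {
  set.seed(5)
  rec <- recording(matrix(rnorm(4 * 100), 4), 100, letters[1:4])
  avg <- rereference(rec)
  expect_lt(max(abs(colSums(avg$samples))), 1e-10 * max(abs(rec$samples)))
  again <- rereference(avg)
  expect_equal(again$samples, avg$samples)

  # two channels [a; b] -> [(a-b)/2; (b-a)/2]
  two <- recording(rbind(a = 1:5, b = rep(0, 5)) + 0, 10, c("a", "b"))
  ref <- rereference(two)
  expect_equal(unname(ref$samples[1, ]), (1:5) / 2)
  expect_equal(unname(ref$samples[2, ]), -(1:5) / 2)

  # rest_approx is a scaled average reference with zero column sums
  rest <- rereference(rec, "rest_approx")
  expect_lt(max(abs(colSums(rest$samples))), 1e-10 * max(abs(rec$samples)))
  expect_equal(rest$samples, 1.25 * avg$samples)
  expect_error(rereference(recording(matrix(1, 1, 10), 10, "A")), ">= 2")
})

test_that("band extraction passes in-band and rejects out-of-band probes", {
  rec6 <- sine_recording(6, fs = 200)
  mid <- interior(rec6)
  theta <- extract_band(rec6, band_definition("theta", 4, 8))
  expect_equal(sd(theta$samples[1, mid]) / sd(rec6$samples[1, mid]), 1,
               tolerance = 0.02)
  beta <- extract_band(rec6, band_definition("beta", 14, 30))
  atten_db <- 20 * log10(sd(beta$samples[1, mid]) / sd(rec6$samples[1, mid]))
  expect_lt(atten_db, -40)

  full <- extract_band(rec6, band_definition("full", 0.5, 100))
  expect_equal(full$samples, rec6$samples)
  expect_error(
    extract_band(sine_recording(6, fs = 100),
                 band_definition("gamma", 30, 100)),
    "Nyquist")
})

test_that("white-noise band powers are proportional to bandwidths", {
  set.seed(6)
  rec <- recording(matrix(rnorm(250 * 120), 1), 250, "A")
  psd <- welch_psd(rec, window_s = 4)
  beta <- band_power(psd, band_definition("beta", 14, 30))
  theta <- band_power(psd, band_definition("theta", 4, 8))
  expect_equal(unname(beta / theta), 16 / 4, tolerance = 0.10)
})

test_that("segmentation partitions a recording exactly", {
  set.seed(7)
  rec <- recording(matrix(rnorm(2 * 18000), 2), 100, c("A", "B"))  # 180 s
  wins <- segment_windows(rec)
  expect_length(wins, 6L)
  expect_equal(vapply(wins, function(w) w$window_start_s, numeric(1)),
               seq(0, 150, by = 30))
  glued <- do.call(cbind, lapply(wins, function(w) w$samples))
  expect_identical(glued, rec$samples)

  short <- recording(matrix(rnorm(2 * 5000), 2), 100, c("A", "B"))
  expect_error(segment_windows(short), "exceeds recording end")
  expect_error(window_spec(30, c(0, 10)), "overlap")
})
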