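test_that("fGn has the exact fractional autocovariance at lag 1", {
  # closed form: rho(1) = (2^(2H) - 2) / 2
  x <- generate_fgn(fgn_spec(2^16, hurst = 0.7, seed = 3))
  r1 <- acf(x, plot = FALSE, lag.max = 1)$acf[2]
  expect_equal(r1, 2^(2 * 0.7 - 1) - 1, tolerance = 0.02 / 0.32)
  expect_equal(sd(x), 1, tolerance = 0.02)

  # H = 0.5 is white noise: |r1| < 3/sqrt(n)
  y <- generate_fgn(fgn_spec(2^14, hurst = 0.5, seed = 4))
  expect_lt(abs(acf(y, plot = FALSE, lag.max = 1)$acf[2]), 3 / sqrt(2^14))
})

test_that("generators are deterministic under a fixed seed", {
  sp <- fgn_spec(4096, hurst = 0.65, seed = 11)
  expect_identical(generate_fgn(sp), generate_fgn(sp))
  expect_identical(generate_fbm_path(sp), generate_fbm_path(sp))
  expect_identical(generate_binomial_cascade(10, 0.7, seed = 9),
                   generate_binomial_cascade(10, 0.7, seed = 9))
})

test_that("fBm path is the cumulative sum of fGn", {
  sp <- fgn_spec(1024, hurst = 0.4, seed = 2)
  expect_equal(generate_fbm_path(sp), cumsum(generate_fgn(sp)))
})

test_that("aggregated-variance scaling of fGn matches var ~ m^(2H-2)", {
  for (H in c(0.3, 0.5, 0.7)) {
    x <- generate_fgn(fgn_spec(2^16, hurst = H, seed = 21))
    ms <- c(1, 4, 16, 64)
    v <- vapply(ms, function(m) {
      blocks <- colMeans(matrix(x[seq_len((2^16 %/% m) * m)], nrow = m))
      var(blocks)
    }, numeric(1))
    slope <- coef(lm(log(v) ~ log(ms)))[2]
    expect_equal(unname(slope), 2 * H - 2, tolerance = 0.12)
  }
})

test_that("fgn_spec validates its invariants", {
  expect_error(fgn_spec(8, 0.5), "n_samples")
  expect_error(fgn_spec(100, 1.0), "hurst")
  expect_error(fgn_spec(100, 0), "hurst")
  expect_error(fgn_spec(100, 0.5, sigma = -1), "sigma")
})

test_that("binomial cascade conserves mass and has dyadic length", {
  m <- generate_binomial_cascade(12, weight_p = 0.7, seed = 5)
  expect_length(m, 2^12)
  expect_equal(sum(m), 1)
  expect_true(all(m > 0))
  expect_error(generate_binomial_cascade(3, 0.7), "n_levels")
  expect_error(generate_binomial_cascade(10, 0.4), "weight_p")
  expect_error(generate_binomial_cascade(10, 1.0), "weight_p")
})

test_that("cascade scaling follows the analytic zeta(q) closed form", {
  # H(q) = (tau(q) + 1)/q with tau(q) = -log2(p^q + (1-p)^q)
  m <- generate_binomial_cascade(14, weight_p = 0.7, seed = 2)
  fit <- ghe(cumsum(m), q = 1:5)
  ana <- cascade_scaling_exponents(1:5, 0.7)
  expect_equal(fit$table$hurst, ana$H_q, tolerance = 0.08)
  # near-uniform limit: H(q) flat in q
  m2 <- generate_binomial_cascade(14, weight_p = 0.501, seed = 2)
  fit2 <- ghe(cumsum(m2), q = 1:5)
  expect_lt(diff(range(fit2$table$hurst)), 0.02)
})

test_that("cohort generator mirrors the default roster composition", {
  roster <- default_roster()
  expect_equal(nrow(roster), 23L)
  expect_equal(as.integer(table(roster$group)[c("C", "N", "O")]),
               c(9L, 5L, 9L))
  lh <- table(roster$group[roster$handedness == "L"])
  expect_equal(as.integer(lh["O"]), 3L)
  expect_equal(as.integer(lh["C"]), 1L)
  expect_false("N" %in% names(lh))
})

test_that("recordings have the contracted geometry and determinism", {
  spec <- cohort_spec(n_channels = 4, fs = 100, duration_s = 30, seed = 8)
  rec <- generate_recording(spec, spec$subjects[1, ])
  expect_equal(dim(rec$samples), c(4L, 3000L))
  expect_equal(rec$channel_labels, montage_1020(4)$label)
  rec2 <- generate_recording(spec, spec$subjects[1, ])
  expect_identical(rec$samples, rec2$samples)
  bad <- spec$subjects[1, ]; bad$group <- "X"
  expect_error(generate_recording(spec, bad), "unknown group")
})

test_that("generated group effect is recovered by the estimator", {
  spec <- cohort_spec(n_channels = 3, fs = 100, duration_s = 120,
                      group_hurst = c(C = 0.7, N = 0.5, O = 0.72),
                      line_noise = FALSE, drift = FALSE, ocular = FALSE,
                      band_gains = c(alpha = 0), seed = 31)
  med <- vapply(c("C1", "N1"), function(sid) {
    rec <- generate_recording(spec,
                              spec$subjects[spec$subjects$subject_id == sid, ])
    median(apply(rec$samples, 1, function(ch) coef(ghe(ch, q = 2))))
  }, numeric(1))
  expect_gt(med["C1"], med["N1"])
  expect_equal(unname(med["C1"]), 0.7, tolerance = 0.08)
  expect_equal(unname(med["N1"]), 0.5, tolerance = 0.08)
})
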