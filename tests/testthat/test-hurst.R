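test_that("structure function agrees with a brute-force double loop", {
  set.seed(14)
  x <- rnorm(800)
  for (q in c(1, 1.5, 2, 3)) for (tau in c(1, 7, 50)) {
    brute <- mean(vapply(seq_len(length(x) - tau), function(t)
      abs(x[t + tau] - x[t])^q, numeric(1)))
    expect_equal(structure_function(x, q, tau), brute,
                 tolerance = 1e-12)
  }
  # linear ramp X(t) = t: K_1(3) = 3 exactly; constant series: 0
  expect_equal(structure_function(as.numeric(1:50), 1, 3), 3)
  expect_equal(structure_function(rep(2, 50), 3, 5), 0)
  expect_equal(structure_function(x, 2, 0), 0)
  expect_error(structure_function(x, 2, 800), "length")
  # q = 2 on iid: flat in tau at ~ 2 var
  expect_equal(structure_function(x, 2, 10) / (2 * var(x)), 1,
               tolerance = 0.1)
})

test_that("structure function is invariant under time reversal", {
  set.seed(15)
  x <- cumsum(rnorm(500))
  for (tau in c(1, 5, 19))
    expect_identical(structure_function(x, 2, tau),
                     structure_function(rev(x), 2, tau))
})

test_that("GHE estimates are exactly affine-invariant", {
  set.seed(16)
  x <- cumsum(rnorm(3000))
  f1 <- ghe(x, q = 1:3)
  f2 <- ghe(-2.5 * x + 40, q = 1:3)
  expect_equal(f1$table$hurst, f2$table$hurst, tolerance = 1e-10)
})

test_that("GHE recovers the generator Hurst exponent on fBm paths", {
  for (H in c(0.3, 0.5, 0.7)) {
    hs <- vapply(1:5, function(s)
      coef(ghe(generate_fbm_path(fgn_spec(50000, H, seed = s)), q = 2)),
      numeric(1))
    expect_equal(mean(hs), H, tolerance = 0.03)
  }
})

test_that("fBm is monofractal: H(q) flat across q", {
  x <- generate_fbm_path(fgn_spec(2^16, 0.6, seed = 17))
  fit <- ghe(x, q = 1:5)
  expect_lt(max(abs(fit$table$hurst - fit$table$hurst[2])), 0.03)
  expect_true(all(fit$table$fit_r2 > 0.99))
})

test_that("GHE rejects degenerate inputs", {
  expect_error(ghe(rep(1, 500)), "zero variance")
  expect_error(ghe(rnorm(50)), "too short")
  expect_error(ghe(cumsum(rnorm(500)), q = c(1, -2)), "positive")
})

test_that("MFDFA recovers noise-scale and walk-scale exponents", {
  x <- generate_fgn(fgn_spec(2^16, 0.7, seed = 18))
  expect_equal(unname(coef(mfdfa(x, q = 2))), 0.7, tolerance = 0.07)
  # integrated input: h(2) = H + 1
  expect_equal(unname(coef(mfdfa(cumsum(x), q = 2))), 1.7, tolerance = 0.1)
})

test_that("noise-scale estimates agree with an independent R/S estimator", {
  # pracma implements rescaled-range and aggregated-variance Hurst
  # estimators; they should agree with our MFDFA h(2) on the same fGn
  x <- generate_fgn(fgn_spec(2^15, 0.7, seed = 2))
  rs <- pracma::hurstexp(x, display = FALSE)
  expect_equal(unname(coef(mfdfa(x, q = 2))), rs$Hal, tolerance = 0.1)
  # and the walk-scale GHE on the integrated series matches them too
  expect_equal(unname(coef(ghe(cumsum(x), q = 2))), rs$Hal,
               tolerance = 0.1)
})

test_that("shuffling collapses MFDFA scaling to 0.5", {
  x <- generate_fgn(fgn_spec(2^16, 0.7, seed = 19))
  sh <- shuffle_surrogate(x, seed = 20)
  expect_identical(sort(sh), sort(x))
  expect_false(identical(sh, x))
  expect_identical(shuffle_surrogate(x, seed = 20), sh)
  expect_identical(shuffle_surrogate(3.14, seed = 1), 3.14)
  expect_equal(unname(coef(mfdfa(sh, q = 2))), 0.5, tolerance = 0.07)
})

test_that("persistence classification respects the threshold and tie band", {
  expect_equal(classify_persistence(0.3)$label, "anti-persistent")
  expect_equal(classify_persistence(0.5)$label, "threshold")
  expect_equal(classify_persistence(0.505)$label, "threshold")
  expect_equal(classify_persistence(1.18)$label, "persistent")
  expect_equal(classify_persistence(0.52)$label, "persistent")
  expect_equal(classify_persistence(0.3, threshold_T = 0.2)$label,
               "persistent")
  expect_error(classify_persistence(NaN), "finite")
})

test_that("windowed estimation honours the counting contract", {
  set.seed(21)
  rec <- recording(matrix(cumsum(rnorm(4 * 18000)), 4, byrow = TRUE), 100,
                   c("Fp1", "Cz", "O1", "Pz"))
  res <- windowed_hfd(rec, q = 2)
  expect_equal(nrow(res), 4 * 6)  # channels x windows, full band, one q
  expect_true(all(res$ok))
  expect_setequal(unique(res$window_start_s), seq(0, 150, by = 30))

  # identical channels give identical estimates
  rec2 <- recording(rbind(rec$samples[1, ], rec$samples[1, ]), 100,
                    c("A", "B"))
  res2 <- windowed_hfd(rec2, q = 2)
  h <- matrix(res2$hurst, nrow = 2)
  expect_equal(h[1, ], h[2, ])
})

test_that("decimation is anti-aliased and rate-correct", {
  set.seed(22)
  x <- rnorm(10000)
  dec <- decimate_series(x, 1000, 250)
  expect_equal(dec$fs, 250)
  expect_length(dec$x, 2500)
  noop <- decimate_series(x, 200, 500)
  expect_identical(noop$x, x)
  # a 450 Hz tone must not alias into the decimated band
  t <- seq_len(10000) / 1000
  tone <- sin(2 * pi * 450 * t)
  dtone <- decimate_series(tone, 1000, 250)
  expect_lt(sd(dtone$x), 0.05 * sd(tone))
})
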