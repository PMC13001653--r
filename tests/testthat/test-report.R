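test_that("group summaries match hand computation and preserve ordering", {
  tab <- data.frame(group = rep("C", 3), hurst = c(1, 2, 3))
  s <- summarize_groups(tab)
  expect_equal(s$mean, 2)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$sd, 1)   # sample SD convention
  expect_equal(s$n, 3)

  one <- summarize_groups(data.frame(group = c("C", "N", "O"),
                                     hurst = c(0.7, 0.5, 0.72)))
  expect_equal(one$sd, rep(0, 3))
  expect_equal(one$mean, one$min)

  tab2 <- make_hfd_table(n_per_cell = 5)
  s2 <- summarize_groups(tab2)
  m <- setNames(s2$mean, s2$group)
  expect_gt(m["C"], m["N"])
  expect_gt(m["O"], m["N"])
  expect_error(summarize_groups(data.frame(group = "Z", hurst = 1)),
               "unknown group")
})

test_that("group summaries are invariant to row order and duplication", {
  tab <- make_hfd_table(n_per_cell = 4)
  s1 <- summarize_groups(tab)
  set.seed(26)
  s2 <- summarize_groups(tab[sample(nrow(tab)), ])
  expect_equal(s1[, c("mean", "min", "max", "sd")],
               s2[, c("mean", "min", "max", "sd")])
  dup <- rbind(tab, tab)
  s3 <- summarize_groups(dup)
  expect_equal(s3$mean, s1$mean)
  expect_equal(s3$min, s1$min)
  expect_equal(s3$max, s1$max)
})

test_that("topographic interpolation reproduces electrode values", {
  mont <- montage_1020(32)
  tab <- data.frame(channel = mont$label,
                    hurst = 0.6 + 0.2 * mont$y, group = "C")
  tm <- topomap(tab, mont, group = "C")
  # surface passes through the electrode values
  interp_at <- function(tm, x0, y0) {
    ix <- which.min(abs(tm$grid_x - x0)); iy <- which.min(abs(tm$grid_y - y0))
    tm$grid[ix, iy]
  }
  inner <- which(tm$x^2 + tm$y^2 < 0.9)  # rim electrodes snap outside disc
  vals <- vapply(inner, function(i)
    interp_at(tm, tm$x[i], tm$y[i]), numeric(1))
  expect_equal(vals, tm$values[inner], tolerance = 0.02)

  # frontal (anterior) region above occipital by construction
  front <- tm$grid[, tm$grid_y > 0.5]
  back <- tm$grid[, tm$grid_y < -0.5]
  expect_gt(mean(front, na.rm = TRUE), mean(back, na.rm = TRUE))

  # constant input -> flat surface
  flat <- topomap(data.frame(channel = mont$label, hurst = 0.9), mont)
  expect_equal(range(flat$grid, na.rm = TRUE), c(0.9, 0.9),
               tolerance = 1e-6)

  expect_error(topomap(data.frame(channel = "Cz", hurst = 1), mont),
               "insufficient")
  expect_error(topomap(data.frame(channel = c("Cz", "XX", "Pz"),
                                  hurst = 1:3), mont), "missing montage")
})

test_that("RBF interpolation is exact at the nodes", {
  mont <- montage_1020(20)
  set.seed(27)
  v <- runif(20)
  z <- fractalEEG:::rbf_interpolate(mont$x, mont$y, v, mont$x, mont$y)
  expect_equal(as.numeric(z), v, tolerance = 1e-6)
})

test_that("pipeline config is validated with key paths named", {
  cfg <- pipeline_config()
  expect_error(run_pipeline(pipeline_config(hfd = list(bands = "omega")),
                            tempfile()), "hfd.bands")
  bad <- cfg; bad$welch <- NULL
  expect_error(run_pipeline(bad, tempfile()), "welch")
  expect_error(run_pipeline(pipeline_config(reference =
                                              list(method = "mastoid")),
                            tempfile()), "reference.method")
})

test_that("the shipped example YAML parses into a valid configuration", {
  path <- system.file("extdata", "pipeline_example.yaml",
                      package = "fractalEEG")
  cfg <- yaml::read_yaml(path)
  expect_true(all(c("cohort", "filters", "reference", "welch", "hfd",
                    "windows", "stats", "seed") %in% names(cfg)))
  expect_equal(cfg$welch$window_s, 8)
  expect_equal(unlist(cfg$windows$start_times_s), seq(0, 150, by = 30))
})

test_that("prefrontal channel subset is the documented default", {
  expect_setequal(prefrontal_channels(),
                  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8"))
  expect_true(all(prefrontal_channels() %in% montage_1020(63)$label))
})

test_that("montage covers 63 uniquely-labelled electrodes with regions", {
  mont <- montage_1020(63)
  expect_equal(nrow(mont), 63)
  expect_false(anyDuplicated(mont$label) > 0)
  expect_true(all(mont$x^2 + mont$y^2 <= 1 + 1e-9))
  expect_setequal(unique(mont$region),
                  c("frontal", "central", "temporal", "parietal",
                    "occipital"))
  expect_error(scalp_region("QQ7"), "unrecognised")
})
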