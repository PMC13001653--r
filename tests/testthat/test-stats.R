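test_that("Kruskal-Wallis matches the hand rank computation", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$statistic, 7.2)
  expect_equal(res$p_value, pchisq(7.2, df = 2, lower.tail = FALSE))
  expect_equal(res$df, 2)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "degenerate ties")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "zero observations")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(23)
  g <- list(rnorm(12), rnorm(12, 0.5), rnorm(12, 1))
  r1 <- kruskal_wallis(g)
  r2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v)))
  expect_equal(r1$statistic, r2$statistic)

  a <- rnorm(15); b <- rnorm(15, 0.4)
  w1 <- wilcoxon_signed_rank(a, b)
  # monotone transform of the differences preserves signs and rank order
  d <- a - b
  d2 <- sign(d) * abs(d)^3
  w2 <- wilcoxon_signed_rank(d2, rep(0, 15))
  expect_equal(w1$statistic, w2$statistic)
})

test_that("signed-rank statistic matches exhaustive enumeration", {
  a <- c(1, 2, 3, 4, 5, 0)
  b <- c(0, 0, 0, 0, 0, 6)   # differences 1,2,3,4,5,-6
  res <- wilcoxon_signed_rank(a, b)
  d <- a - b
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  expect_equal(res$V, V_obs)
  # exact two-sided p over all 2^6 sign patterns
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  Vs <- as.matrix(signs) %*% r
  mu <- sum(r) / 2
  p_exact <- mean(abs(Vs - mu) >= abs(V_obs - mu))
  expect_equal(res$p_value, p_exact, tolerance = 0.1)
  # agreement with the reference normal-approximation implementation
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                     correct = TRUE))
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-10)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
})

test_that("paired t matches the hand formula", {
  d <- c(1, -1, 2, -2, 3)
  res <- paired_t(d, rep(0, 5))
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(res$statistic, 0.6470, tolerance = 1e-4)
  expect_error(paired_t(1:5 + 1, 1:5), "zero-variance")
  expect_error(paired_t(1:2, 1:2), "n >= 3")
})

test_that("factorial ANOVA isolates constructed effects", {
  # balanced 2x2, additive, near-zero noise: huge main effects, null interaction
  set.seed(24)
  grid <- expand.grid(group = c("C", "N"), sex = c("M", "F"),
                      rep = 1:6, stringsAsFactors = FALSE)
  grid$hurst <- 0.5 + 0.2 * (grid$group == "C") + 0.1 * (grid$sex == "M") +
    rnorm(nrow(grid), sd = 1e-4)
  grid$subject_id <- paste0(grid$group, grid$rep)
  grid$band <- "full"; grid$channel <- "Cz"; grid$window_start_s <- 0
  grid$q <- 2; grid$handedness <- "R"
  grid$region <- "central"; grid$alpha_excluded <- FALSE
  class(grid) <- c("hfd_table", "data.frame")

  res <- nway_anova(grid, factors = c("group", "sex"),
                    interactions = list(c("group", "sex")))
  expect_lt(res$tests[["group"]]$p_value, 1e-10)
  expect_lt(res$tests[["sex"]]$p_value, 1e-10)
  expect_gt(res$tests[["group:sex"]]$p_value, 0.01)

  # row-permutation invariance
  perm <- grid[sample(nrow(grid)), ]
  class(perm) <- c("hfd_table", "data.frame")
  res2 <- nway_anova(perm, factors = c("group", "sex"))
  expect_equal(res2$anova_table$F, nway_anova(grid,
               factors = c("group", "sex"))$anova_table$F)

  # cell means recover the construction
  ci <- res$cell_ci
  cm <- ci$mean[ci$group == "C" & ci$sex == "M"]
  expect_equal(cm, 0.8, tolerance = 1e-3)
})

test_that("ANOVA rejects degenerate designs", {
  tab <- make_hfd_table()
  tab$sex <- "F"
  class(tab) <- c("hfd_table", "data.frame")
  expect_error(nway_anova(tab, factors = c("group", "sex")),
               "fewer than 2")
})

test_that("alpha-band rows are excluded from inference", {
  tab <- make_hfd_table(bands = c("full", "alpha"))
  res <- nway_anova(tab, factors = "group")
  expect_equal(res$tests[["group"]]$n, sum(tab$band != "alpha"))
  expect_equal(res$tests[["group"]]$n, nrow(tab) / 2)
})

test_that("configured group effect is detected by the battery", {
  # handedness and sex are confounded with group in this small fixture, so
  # restrict the factorial part to the group factor
  tab <- make_hfd_table(n_per_cell = 6)
  res <- stat_battery(tab, factors = "group", seed = 1)
  expect_lt(res$kruskal[["group"]]$p_value, 0.05)
  expect_lt(res$anova$tests[["group"]]$p_value, 0.05)
  expect_equal(res$kfold$k, 10)
})

test_that("per-band Pearson correlation applies the Bonferroni threshold", {
  set.seed(25)
  bands <- lapply(stats::setNames(nm = c("delta", "theta", "beta",
                                         "gamma", "full")),
                  function(b) {
    h <- rnorm(30)
    list(hurst = h, power = h * 0.5 + rnorm(30, sd = 2))
  })
  res <- pearson_bonferroni(bands, alpha = 0.05)
  expect_length(res, 5)
  expect_equal(res[["delta"]]$adjusted_alpha, 0.01)
  perfect <- list(full = list(hurst = 1:10, power = 2 * (1:10) + 1))
  expect_equal(pearson_bonferroni(perfect)$full$statistic, 1)
  expect_error(pearson_bonferroni(
    list(full = list(hurst = rep(1, 10), power = 1:10))), "constant")
})

test_that("k-fold validation partitions exactly and is deterministic", {
  tab <- data.frame(hurst = rnorm(53, 0.6, 0.05))
  res <- kfold_validation(tab, k = 10, seed = 6)
  expect_equal(nrow(res$folds), 10)
  expect_equal(sum(res$folds$n_heldout), 53)
  expect_true(all(res$folds$n_heldout %in% c(5, 6)))
  expect_equal(sort(unique(res$assignment)), 1:10)
  expect_identical(kfold_validation(tab, k = 10, seed = 6)$assignment,
                   res$assignment)

  # leave-one-out degenerate case
  loo <- kfold_validation(data.frame(hurst = rnorm(8)), k = 8, seed = 1)
  expect_true(all(loo$folds$n_heldout == 1))
  # constant table -> zero dispersion
  const <- kfold_validation(data.frame(hurst = rep(0.7, 20)), k = 10,
                            seed = 2)
  expect_equal(const$sd_heldout, 0)
  expect_error(kfold_validation(data.frame(hurst = rnorm(5)), k = 10),
               "exceed")
})
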