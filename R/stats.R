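#' Assemble a Hurst-exponent analysis table
#'
#' Joins windowed Hurst results with subject metadata and adds the coarse
#' scalp region per electrode plus an `alpha_excluded` flag: because of the
#' dominant power distribution of the alpha band, rows in the 8-13 Hz range
#' are excluded from inferential tests (the rows are retained, flagged, and
#' filtered by each test wrapper).
#'
#' @param hfd data frame from [windowed_hfd()] (possibly row-bound over
#'   subjects).
#' @param meta roster data frame with `subject_id`, `group`, `sex`,
#'   `handedness`, `age`.
#' @return Data frame of class `hfd_table`.
#' @export
hfd_table <- function(hfd, meta) {
  need <- c("subject_id", "channel", "band", "window_start_s", "q", "hurst")
  miss <- setdiff(need, names(hfd))
  if (length(miss)) stop("hfd missing column(s): ", paste(miss, collapse = ", "))
  out <- merge(hfd, meta[, c("subject_id", "group", "sex", "handedness")],
               by = "subject_id", sort = FALSE)
  bad <- setdiff(unique(out$group), c("C", "N", "O"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  out$region <- scalp_region(out$channel)
  out$alpha_excluded <- out$band == "alpha"
  class(out) <- c("hfd_table", "data.frame")
  out
}

inferential_rows <- function(table) {
  out <- table[!table$alpha_excluded & !is.na(table$hurst), , drop = FALSE]
  if (!nrow(out)) stop("no usable rows after alpha-band exclusion")
  out
}

stat_result <- function(test, statistic_name, statistic, p_value, factors,
                        n, correction = "none", extra = list()) {
  structure(c(list(test = test, statistic_name = statistic_name,
                   statistic = unname(statistic), p_value = unname(p_value),
                   factors = factors, n = n, correction = correction),
              extra),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: %s = %.6g, p = %.4g (n = %d%s)\n",
              x$test, paste(x$factors, collapse = ", "),
              x$statistic_name, x$statistic, x$p_value, x$n,
              if (x$correction != "none")
                paste0(", correction: ", x$correction) else ""))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based comparison of two or more independent samples with tie
#' correction; the H statistic is referred to a chi-square distribution
#' with (groups - 1) degrees of freedom. Completely tied data (all values
#' identical) make the tie correction degenerate and raise an error.
#'
#' @param samples list of numeric vectors (>= 2 groups) or a two-column
#'   `data.frame`/formula interface via `values` and `groups`.
#' @param factor_label label stored in the result (default "group").
#' @return A `stat_test_result` with the chi-square statistic.
#' @export
kruskal_wallis <- function(samples, factor_label = "group") {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need a list of >= 2 groups")
  if (any(lengths(samples) == 0L)) stop("a group has zero observations")
  values <- unlist(samples, use.names = FALSE)
  if (length(unique(values)) == 1L)
    stop("degenerate ties: all observations identical")
  g <- factor(rep(seq_along(samples), lengths(samples)))
  kt <- stats::kruskal.test(values, g)
  stat_result("Kruskal-Wallis", "chi-square", kt$statistic, kt$p.value,
              factor_label, length(values),
              extra = list(df = unname(kt$parameter)))
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Paired rank test: zero differences are dropped, the remaining absolute
#' differences are ranked with midranks for ties, and the signed-rank sum
#' is standardized with tie-corrected variance and a 0.5 continuity
#' correction, giving a z statistic and a two-sided normal p-value.
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @param factor_label label stored in the result.
#' @return A `stat_test_result` with the z statistic (and the signed-rank
#'   sum `V` in `$V`).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 factor_label = "pairing") {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0L) stop("all paired differences are zero")
  if (length(d) < 6L)
    stop("need >= 6 non-zero differences for the normal approximation")
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(V - mu) * 0.5
  z <- (V - mu - cc) / sqrt(sig2)
  p <- 2 * stats::pnorm(-abs(z))
  stat_result("Wilcoxon signed-rank", "z", z, min(1, p), factor_label, n,
              extra = list(V = V))
}

#' Paired t test
#'
#' Classical two-sided paired t on the differences.
#'
#' @param paired_a,paired_b equal-length numeric vectors, n >= 3.
#' @param factor_label label stored in the result.
#' @return A `stat_test_result` with the t statistic.
#' @export
paired_t <- function(paired_a, paired_b, factor_label = "pairing") {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length")
  if (length(paired_a) < 3L) stop("need n >= 3 pairs")
  d <- paired_a - paired_b
  if (stats::sd(d) == 0)
    stop("zero-variance differences: t statistic undefined")
  tt <- stats::t.test(paired_a, paired_b, paired = TRUE)
  stat_result("paired t", "t", tt$statistic, tt$p.value, factor_label,
              length(d), extra = list(df = unname(tt$parameter)))
}

#' Factorial n-way ANOVA on windowed Hurst exponents
#'
#' Fits a fixed-effects linear model of `hurst` on the requested factors
#' (any of `group`, `handedness`, `sex`, `region`, `band`) with up to
#' two-way interactions, and reports type-II F tests per term. Alpha-band
#' rows are excluded. Confidence intervals of the cell means over all
#' factor-level combinations are returned alongside (the usual
#' interaction-surface display). Rank-deficient designs are reported with
#' the aliased terms named.
#'
#' @param table an [hfd_table()].
#' @param factors character vector of factor names.
#' @param interactions list of length-2 character vectors naming requested
#'   two-way interactions (default: none).
#' @return List with `tests` (list of `stat_test_result`), `anova_table`
#'   (data frame), `cell_ci` (data frame of cell means with 95 percent
#'   confidence intervals), `model` (the `lm` fit).
#' @export
nway_anova <- function(table, factors = c("group", "handedness", "sex",
                                          "region", "band"),
                       interactions = list()) {
  stopifnot(inherits(table, "hfd_table"))
  dat <- inferential_rows(table)
  factors <- unique(factors)
  ok <- vapply(factors, function(f)
    length(unique(dat[[f]])) >= 2L, logical(1))
  if (!all(ok))
    stop("factor(s) with fewer than 2 observed levels: ",
         paste(factors[!ok], collapse = ", "))
  for (f in factors) dat[[f]] <- factor(dat[[f]])

  terms <- factors
  for (ia in interactions) {
    if (length(ia) != 2L || !all(ia %in% factors))
      stop("interactions must be pairs of requested factors")
    terms <- c(terms, paste(ia, collapse = ":"))
  }
  fml <- stats::reformulate(terms, response = "hurst")
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  a2 <- car::Anova(fit, type = 2)
  rows <- rownames(a2)
  keep <- !rows %in% c("Residuals")
  tests <- lapply(which(keep), function(i)
    stat_result("n-way ANOVA", "F", a2$`F value`[i], a2$`Pr(>F)`[i],
                rows[i], nrow(dat),
                extra = list(df = a2$Df[i], sum_sq = a2$`Sum Sq`[i])))
  names(tests) <- rows[keep]

  cells <- stats::aggregate(dat$hurst, by = dat[factors],
                            FUN = function(v)
                              c(mean = mean(v), sd = stats::sd(v),
                                n = length(v)))
  ci <- data.frame(cells[factors],
                   mean = cells$x[, "mean"], sd = cells$x[, "sd"],
                   n = cells$x[, "n"])
  se <- ifelse(ci$n > 1, ci$sd / sqrt(ci$n), NA)
  tq <- stats::qt(0.975, pmax(ci$n - 1, 1))
  ci$ci_lo <- ci$mean - tq * se
  ci$ci_hi <- ci$mean + tq * se

  list(tests = tests,
       anova_table = data.frame(term = rows, df = a2$Df,
                                sum_sq = a2$`Sum Sq`,
                                F = a2$`F value`, p = a2$`Pr(>F)`),
       cell_ci = ci, model = fit)
}

#' Per-band Pearson correlation with Bonferroni correction
#'
#' Correlates Hurst exponents with band powers within each band and applies
#' a Bonferroni-adjusted significance threshold `alpha / m` across the m
#' bands tested.
#'
#' @param x_by_band named list; each element a data frame or list with
#'   numeric `hurst` and `power` of equal length (n >= 4).
#' @param alpha family-wise error target (default 0.05).
#' @return List of `stat_test_result`, one per band, each carrying
#'   `$significant` under the adjusted threshold and
#'   `$adjusted_alpha`.
#' @export
pearson_bonferroni <- function(x_by_band, alpha = 0.05) {
  m <- length(x_by_band)
  if (m < 1L) stop("need at least one band")
  adj <- alpha / m
  out <- lapply(names(x_by_band), function(b) {
    d <- x_by_band[[b]]
    h <- d$hurst; p <- d$power
    if (length(h) < 4L) stop("band '", b, "' has fewer than 4 pairs")
    if (stats::sd(h) == 0 || stats::sd(p) == 0)
      stop("band '", b, "' has a constant input vector")
    ct <- stats::cor.test(h, p, method = "pearson")
    stat_result("Pearson correlation", "r", ct$estimate, ct$p.value,
                c("band", b), length(h), correction = "bonferroni",
                extra = list(significant = ct$p.value < adj,
                             adjusted_alpha = adj))
  })
  stats::setNames(out, names(x_by_band))
}

#' k-fold validation of the mean Hurst exponent
#'
#' Splits the rows into k disjoint, exhaustive folds of equal size (within
#' one) by a seeded permutation. For each fold the held-in mean Hurst
#' exponent is computed from the other k-1 folds and compared with the
#' held-out fold's mean; every row is held out exactly once and the k
#' held-out evaluations are summarized by their mean and SD.
#'
#' @param table an [hfd_table()] or any data frame with a `hurst` column.
#' @param k number of folds (default 10); `k = nrow` gives leave-one-out.
#' @param seed permutation seed.
#' @return List with `folds` (data frame: fold, n_heldout, heldin_mean,
#'   heldout_mean, abs_error), `mean_heldout`, `sd_heldout`, `k`,
#'   `assignment` (fold index per row).
#' @export
kfold_validation <- function(table, k = 10L, seed = 1L) {
  h <- table$hurst
  h <- h[!is.na(h)]
  n <- length(h)
  if (k > n) stop("k must not exceed the number of rows (", n, ")")
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))
  folds <- do.call(rbind, lapply(seq_len(k), function(f) {
    held_out <- h[fold == f]
    held_in <- h[fold != f]
    data.frame(fold = f, n_heldout = length(held_out),
               heldin_mean = mean(held_in),
               heldout_mean = mean(held_out),
               abs_error = abs(mean(held_in) - mean(held_out)))
  }))
  list(folds = folds, mean_heldout = mean(folds$heldout_mean),
       sd_heldout = stats::sd(folds$heldout_mean), k = k,
       assignment = fold)
}

#' Run the full statistical battery on an analysis table
#'
#' Convenience wrapper reproducing the standard report layout: group-wise
#' Kruskal-Wallis on the full-spectrum Hurst exponents, Kruskal-Wallis per
#' factor, paired tests (Wilcoxon signed-rank and paired t) for two-level
#' factors paired within subject-window cells, the factorial ANOVA, and
#' k-fold validation. Alpha-band rows are excluded throughout.
#'
#' @param table an [hfd_table()].
#' @param factors factors for the ANOVA (defaults to those with >= 2
#'   observed levels among group, handedness, sex, region, band).
#' @param k folds for validation.
#' @param seed seed for the fold assignment.
#' @return List with elements `kruskal`, `paired`, `anova`, `kfold`.
#' @export
stat_battery <- function(table, factors = NULL, k = 10L, seed = 1L) {
  stopifnot(inherits(table, "hfd_table"))
  dat <- inferential_rows(table)
  if (is.null(factors)) {
    cand <- c("group", "handedness", "sex", "region", "band")
    factors <- cand[vapply(cand, function(f)
      length(unique(dat[[f]])) >= 2L, logical(1))]
  }

  kw <- lapply(factors, function(f) {
    kruskal_wallis(split(dat$hurst, dat[[f]]), factor_label = f)
  })
  names(kw) <- factors

  paired <- list()
  for (f in intersect(c("handedness", "sex"), factors)) {
    lv <- sort(unique(as.character(dat[[f]])))
    if (length(lv) != 2L) next
    cell <- interaction(dat$subject_id, dat$window_start_s, dat$band,
                        drop = TRUE)
    m1 <- tapply(dat$hurst[dat[[f]] == lv[1]], cell[dat[[f]] == lv[1]], mean)
    m2 <- tapply(dat$hurst[dat[[f]] == lv[2]], cell[dat[[f]] == lv[2]], mean)
    # pair level means across window x band cells present for both levels
    g1 <- tapply(dat$hurst[dat[[f]] == lv[1]],
                 interaction(dat$window_start_s, dat$band,
                             drop = TRUE)[dat[[f]] == lv[1]], mean)
    g2 <- tapply(dat$hurst[dat[[f]] == lv[2]],
                 interaction(dat$window_start_s, dat$band,
                             drop = TRUE)[dat[[f]] == lv[2]], mean)
    common <- intersect(names(g1), names(g2))
    if (length(common) >= 6L) {
      paired[[f]] <- list(
        wilcoxon = wilcoxon_signed_rank(g1[common], g2[common], f),
        t = paired_t(g1[common], g2[common], f))
    }
  }

  av <- if (length(factors) >= 1L) nway_anova(table, factors) else NULL
  kf <- kfold_validation(dat, k = min(k, nrow(dat)), seed = seed)
  list(kruskal = kw, paired = paired, anova = av, kfold = kf)
}
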