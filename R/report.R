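#' Group summaries of Hurst exponents
#'
#' Per-group mean, minimum, maximum and sample (n-1) standard deviation of
#' the Hurst estimates, computed over all channels and windows of the
#' full-spectrum band (or of the whole table when no `band` column is
#' present). Optionally restricted to a channel subset, e.g. the prefrontal
#' electrodes.
#'
#' @param table an [hfd_table()] or data frame with `group` and `hurst`.
#' @param channels optional character vector restricting to these channels.
#' @param band which band to summarize (default `"full"` when present).
#' @return Data frame with columns `group`, `mean`, `min`, `max`, `sd`,
#'   `n`.
#' @export
summarize_groups <- function(table, channels = NULL, band = "full") {
  if (!nrow(table)) stop("empty table")
  bad <- setdiff(unique(table$group), c("C", "N", "O"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  dat <- table
  if (!is.null(dat$band) && band %in% dat$band)
    dat <- dat[dat$band == band, , drop = FALSE]
  if (!is.null(channels)) dat <- dat[dat$channel %in% channels, , drop = FALSE]
  dat <- dat[!is.na(dat$hurst), , drop = FALSE]
  out <- do.call(rbind, lapply(split(dat$hurst, dat$group), function(v)
    data.frame(mean = mean(v), min = min(v), max = max(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Default prefrontal electrode subset
#' @return Character vector of prefrontal 10-20 labels.
#' @export
prefrontal_channels <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8")
}

# Gaussian radial-basis interpolation passing exactly through the nodes.
# The node mean is removed first and added back after interpolation, so a
# constant field interpolates to exactly that constant everywhere.
rbf_interpolate <- function(px, py, values, gx, gy) {
  mu <- mean(values)
  d2 <- outer(px, px, function(a, b) (a - b)^2) +
    outer(py, py, function(a, b) (a - b)^2)
  eps2 <- stats::median(d2[d2 > 0])
  phi <- exp(-d2 / eps2)
  wts <- solve(phi + diag(1e-10, length(px)), values - mu)
  g2 <- outer(gx, px, function(a, b) (a - b)^2)
  gy2 <- outer(gy, py, function(a, b) (a - b)^2)
  mu + (exp(-(g2 + gy2) / eps2)) %*% wts
}

#' Topographic scalp map of mean Hurst exponents
#'
#' Averages the Hurst estimates per electrode for one group, interpolates
#' them over the scalp disc with Gaussian radial basis functions (the
#' surface passes through the electrode values exactly, up to numerical
#' tolerance), and optionally renders a head-outline figure with electrode
#' markers to PNG. The interpolated grid is returned (and can be written as
#' CSV) so figure content is numerically testable.
#'
#' @param table data frame with `channel`, `hurst` and (optionally)
#'   `group` columns.
#' @param montage montage data frame covering all channels in `table`.
#' @param group group label to select (ignored when the table has no
#'   `group` column).
#' @param grid_n grid resolution per axis (default 67).
#' @param png_path optional output PNG path; no figure is drawn when
#'   `NULL`.
#' @return Object of class `topo_map`: `labels`, `x`, `y`, `values`
#'   (per-electrode means), `grid_x`, `grid_y`, `grid` (matrix with NA
#'   outside the disc), `group`.
#' @export
topomap <- function(table, montage, group = NULL, grid_n = 67L,
                    png_path = NULL) {
  dat <- table
  if (!is.null(group) && !is.null(dat$group))
    dat <- dat[dat$group == group, , drop = FALSE]
  dat <- dat[!is.na(dat$hurst), , drop = FALSE]
  if (!nrow(dat)) stop("no rows for group ", group)
  means <- tapply(dat$hurst, dat$channel, mean)
  labs <- names(means)
  miss <- setdiff(labs, montage$label)
  if (length(miss))
    stop("electrode(s) missing montage coordinates: ",
         paste(miss, collapse = ", "))
  if (length(labs) < 3L)
    stop("insufficient support for interpolation (need >= 3 electrodes)")
  idx <- match(labs, montage$label)
  px <- montage$x[idx]; py <- montage$y[idx]

  gx <- seq(-1, 1, length.out = grid_n)
  gg <- expand.grid(x = gx, y = gx)
  z <- rbf_interpolate(px, py, as.numeric(means), gg$x, gg$y)
  z[gg$x^2 + gg$y^2 > 1] <- NA
  grid <- matrix(z, grid_n, grid_n)

  tm <- structure(list(labels = labs, x = px, y = py,
                       values = as.numeric(means),
                       grid_x = gx, grid_y = gx, grid = grid,
                       group = group),
                  class = "topo_map")
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    plot(tm)
  }
  tm
}

#' @export
plot.topo_map <- function(x, ...) {
  rng <- range(x$values)
  graphics::image(x$grid_x, x$grid_y, x$grid, asp = 1, axes = FALSE,
                  xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = if (!is.null(x$group))
                    paste("Mean Hurst exponent, group", x$group)
                  else "Mean Hurst exponent", ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  graphics::lines(c(-0.08, 0, 0.08), c(0.995, 1.08, 0.995))  # nose
  graphics::points(x$x, x$y, pch = 21, bg = "white", cex = 1.1)
  graphics::mtext(sprintf("range %.4f - %.4f", rng[1], rng[2]), side = 1)
  invisible(x)
}

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], with every
#' stage parameter surfaced: cohort geometry and group Hurst targets,
#' filter edges, reference method, ICA settings, Welch window, estimator
#' settings, statistics options. The default is a reduced-scale synthetic
#' cohort (full 23-subject roster, 8 channels, 100 Hz) that exercises the
#' whole pipeline quickly; pass overrides or edit the YAML to scale up.
#'
#' @param ... named overrides of top-level entries.
#' @return Nested named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cohort = list(n_channels = 8L, fs = 100, duration_s = 180,
                  group_hurst = c(C = 0.70, N = 0.55, O = 0.72),
                  line_noise = FALSE, drift = TRUE, ocular = TRUE),
    filters = list(band_low = 1, band_high = 45, drift_cut = 0.2,
                   line_hz = 60),
    reference = list(method = "average"),
    ica = list(enabled = TRUE, n_components = NULL,
               template_threshold = 0.7, kurtosis_threshold = 5),
    welch = list(window_s = 8),
    hfd = list(estimator = "ghe", q = 1:5, decimate_to_hz = 500,
               bands = character(0)),
    windows = list(length_s = 30, start_times_s = seq(0, 150, by = 30)),
    stats = list(k = 10L),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  cfg
}

validate_config <- function(cfg) {
  need <- c("cohort", "filters", "reference", "welch", "hfd", "windows",
            "stats", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config missing key(s): ", paste(miss, collapse = ", "))
  known_bands <- names(eeg_bands())
  bad <- setdiff(cfg$hfd$bands, known_bands)
  if (length(bad))
    stop("config key hfd.bands: unknown band name(s): ",
         paste(bad, collapse = ", "),
         " (known: ", paste(known_bands, collapse = ", "), ")")
  if (!cfg$reference$method %in% c("average", "rest_approx"))
    stop("config key reference.method must be 'average' or 'rest_approx'")
  if (!cfg$hfd$estimator %in% c("ghe", "mfdfa"))
    stop("config key hfd.estimator must be 'ghe' or 'mfdfa'")
  invisible(cfg)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> preprocess -> spectra -> Hurst estimation -> stats
#' -> report for a configuration (a [pipeline_config()] list or a YAML file
#' with the same keys), writing all artifacts into `out_dir`:
#' `cohort.csv`, `spectra.csv`, `hfd.csv`, `group_summary.csv`,
#' `stats/anova.csv`, `stats/kruskal.csv`, `stats/kfold.csv`,
#' `topo_<group>.png` (+ `topo_<group>.csv` grids) and `provenance.json`
#' with every stage parameter and seed. Outputs are deterministic: the same
#' configuration and seed give byte-identical CSVs.
#'
#' @param config a config list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding `config$seed`.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config$cohort$group_hurst))
    config$cohort$group_hurst <- unlist(config$cohort$group_hurst)
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)

  co <- config$cohort
  args <- list(subjects = default_roster(),
               group_hurst = co$group_hurst,
               n_channels = co$n_channels, fs = co$fs,
               duration_s = co$duration_s,
               line_noise = isTRUE(co$line_noise),
               drift = isTRUE(co$drift),
               ocular = isTRUE(co$ocular),
               seed = config$seed)
  if (!is.null(co$band_gains)) args$band_gains <- unlist(co$band_gains)
  spec <- do.call(cohort_spec, args)
  recs <- generate_cohort(spec)
  write_cohort_csv(spec$subjects, file.path(out_dir, "cohort.csv"))

  wspec <- window_spec(config$windows$length_s,
                       unlist(config$windows$start_times_s))
  bands <- eeg_bands(co$fs)
  hfd_bands <- bands[intersect(unlist(config$hfd$bands), names(bands))]

  spectra <- list(); hfd <- list()
  for (sid in names(recs)) {
    rec <- recs[[sid]]
    f <- config$filters
    cleaned <- apply_filters(rec, band_low = f$band_low,
                             band_high = min(f$band_high, 0.45 * rec$fs),
                             drift_cut = f$drift_cut, line_hz = f$line_hz)
    if (isTRUE(config$ica$enabled)) {
      ica <- remove_ocular_ica(cleaned,
                               n_components = config$ica$n_components,
                               template_threshold = config$ica$template_threshold,
                               kurtosis_threshold = config$ica$kurtosis_threshold,
                               seed = config$seed)
      cleaned <- ica$recording
    }
    cleaned <- rereference(cleaned, config$reference$method)
    spectra[[sid]] <- spectral_summary(cleaned,
                                       window_s = config$welch$window_s)
    hfd[[sid]] <- windowed_hfd(cleaned, wspec, bands = hfd_bands,
                               q = unlist(config$hfd$q),
                               estimator = config$hfd$estimator,
                               decimate_to_hz = config$hfd$decimate_to_hz)
  }
  spectra <- do.call(rbind, spectra)
  hfd <- do.call(rbind, hfd)
  num_fmt <- function(df) {
    for (nm in names(df)) if (is.numeric(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 10, format = "g")
    df
  }
  utils::write.csv(num_fmt(spectra), file.path(out_dir, "spectra.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(num_fmt(hfd), file.path(out_dir, "hfd.csv"),
                   row.names = FALSE, quote = FALSE)

  tab <- hfd_table(hfd, spec$subjects)
  gs <- summarize_groups(tab)
  utils::write.csv(num_fmt(gs), file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  battery <- stat_battery(tab, k = config$stats$k, seed = config$seed)
  utils::write.csv(num_fmt(battery$anova$anova_table),
                   file.path(out_dir, "stats", "anova.csv"),
                   row.names = FALSE, quote = FALSE)
  kw <- do.call(rbind, lapply(names(battery$kruskal), function(f) {
    r <- battery$kruskal[[f]]
    data.frame(factor = f, chi_square = r$statistic, df = r$df,
               p = r$p_value, n = r$n)
  }))
  utils::write.csv(num_fmt(kw), file.path(out_dir, "stats", "kruskal.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(num_fmt(battery$kfold$folds),
                   file.path(out_dir, "stats", "kfold.csv"),
                   row.names = FALSE, quote = FALSE)

  mont <- montage_1020(co$n_channels)
  q2 <- tab[tab$q == min(2, max(tab$q)) & tab$band == "full", ]
  for (g in unique(q2$group)) {
    tm <- topomap(q2, mont, group = g,
                  png_path = file.path(out_dir, paste0("topo_", g, ".png")))
    gr <- tm$grid
    utils::write.csv(
      data.frame(x = rep(tm$grid_x, length(tm$grid_y)),
                 y = rep(tm$grid_y, each = length(tm$grid_x)),
                 hurst = formatC(as.vector(gr), digits = 10, format = "g")),
      file.path(out_dir, paste0("topo_", g, ".csv")),
      row.names = FALSE, quote = FALSE)
  }

  prov <- list(config = config,
               package_version = as.character(utils::packageVersion("fractalEEG")),
               n_subjects = length(recs),
               n_subject_windows = length(recs) *
                 length(wspec$start_times_s))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
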