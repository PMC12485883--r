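#' Run a configured experiment end to end
#'
#' Chains the pipeline stages of one of the three analyses — retention
#' quantification (\code{quantify}), Pearson/Costes colocalization
#' (\code{coloc}) and the STED nearest-neighbor analysis (\code{sted_nn})
#' — on real or simulated inputs (\code{simulate} writes synthetic scenes
#' plus a manifest the other stages consume). All result tables are CSV;
#' a provenance record (\code{provenance.yaml}: configuration, seeds,
#' package version, stages run) accompanies them, so identical
#' configurations reproduce identical outputs.
#'
#' The configuration is a named list (or path to a YAML file) with at
#' least \code{stages} (subset of \code{"simulate"}, \code{"quantify"},
#' \code{"coloc"}, \code{"sted_nn"}), \code{out_dir} and \code{seed}.
#' Stage-specific entries:
#' \describe{
#'   \item{simulate}{\code{n_sheets}, \code{constructs} (named vector of
#'     domain affinities, e.g. \code{c(CD9 = 2, EWI2 = 0)}), \code{shape},
#'     and any \code{\link{simulate_scene}} parameter under \code{scene}.}
#'   \item{quantify / coloc}{\code{manifest} (CSV path; written by
#'     \code{simulate} when chained), \code{pixel_size_nm},
#'     \code{block_px}, \code{n_scrambles}, \code{p_threshold}.}
#'   \item{sted_nn}{\code{red}, \code{longred} (TIFF paths) or
#'     \code{scene} parameters to simulate them; \code{ref_tol},
#'     \code{target_tol}, \code{sweep} (logical).}
#' }
#'
#' The manifest is a CSV with one row per membrane sheet: \code{sheet_id},
#' \code{construct}, \code{condition}, \code{treatment}, \code{replicate},
#' \code{roi_row0}, \code{roi_col0}, \code{roi_side}, \code{bg_row0},
#' \code{bg_col0}, \code{bg_side} and one \code{file_<channel>} column per
#' channel.
#'
#' @param config named list or path to a YAML configuration file.
#' @return Invisibly, a named list of the result data frames per stage.
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("'config' must be a list or a YAML file path")
  stages <- config$stages %||% config$experiment
  if (is.null(stages)) stop("config must name the 'stages' to run")
  known <- c("simulate", "quantify", "coloc", "sted_nn")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (is.null(config$out_dir)) stop("config must set 'out_dir'")
  if (is.null(config$seed)) stop("config must set 'seed'")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # pre-flight: referenced input files must exist before any computation
  for (f in c(config$manifest, config$red, config$longred))
    if (!is.null(f) && !file.exists(f))
      stop("input file not found: ", f)
  if (!is.null(config$manifest)) check_manifest_files(config$manifest)

  results <- list()
  manifest <- config$manifest
  for (stage in stages) {
    results[[stage]] <- switch(
      stage,
      simulate = {
        r <- stage_simulate(config, out_dir)
        manifest <- r$manifest
        r$sheets
      },
      quantify = stage_quantify(config, manifest, out_dir),
      coloc = stage_coloc(config, manifest, out_dir),
      sted_nn = stage_sted_nn(config, out_dir))
  }
  prov <- list(package = "sheetquant",
               version = as.character(utils::packageVersion("sheetquant")),
               stages = as.list(stages),
               seed = config$seed,
               config = config[setdiff(names(config), "out_dir")])
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

check_manifest_files <- function(path) {
  man <- read_manifest(path)
  fcols <- grep("^file_", names(man), value = TRUE)
  for (col in fcols) {
    missing <- man[[col]][!file.exists(man[[col]])]
    if (length(missing))
      stop("manifest references missing file(s): ",
           paste(missing, collapse = ", "))
  }
  invisible(man)
}

stage_simulate <- function(config, out_dir) {
  n_sheets <- config$n_sheets %||% 6L
  constructs <- config$constructs %||% c(CD9 = 2, EWI2 = 0)
  constructs <- unlist(constructs)
  shape <- as.integer(config$shape %||% c(128L, 128L))
  scene_args <- config$scene %||% list()
  roi_side <- config$roi_side %||% 48L
  rows <- list()
  i <- 0L
  for (cn in names(constructs)) for (s in seq_len(n_sheets)) {
    i <- i + 1L
    sheet_id <- sprintf("%s_s%02d", cn, s)
    sdir <- file.path(out_dir, "scenes", sheet_id)
    args <- utils::modifyList(
      list(preset = "epi", shape = shape,
           seed = config$seed + 1000L * match(cn, names(constructs)) + s,
           affinity = unname(constructs[[cn]]),
           n_clusters = 40L + ((s * 37L) %% 120L)),
      scene_args)
    sc <- do.call(simulate_scene, args)
    write_scene(sc, sdir)
    rows[[i]] <- data.frame(
      sheet_id = sheet_id, construct = cn, condition = "aGFP",
      treatment = "none", replicate = ((s - 1L) %% 3L) + 1L,
      roi_row0 = (shape[1] - roi_side) %/% 2L,
      roi_col0 = (shape[2] - roi_side) %/% 2L,
      roi_side = roi_side,
      bg_row0 = 0L, bg_col0 = 0L, bg_side = min(16L, roi_side),
      file_membrane = file.path(sdir, "membrane.tif"),
      file_gfp = file.path(sdir, "gfp.tif"),
      file_ph = file.path(sdir, "ph.tif"))
  }
  sheets <- do.call(rbind, rows)
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(sheets, manifest, row.names = FALSE)
  list(manifest = manifest, sheets = sheets)
}

manifest_channels <- function(man) {
  sub("^file_", "", grep("^file_", names(man), value = TRUE))
}

sheet_roi <- function(row) square_roi(row$roi_row0, row$roi_col0, row$roi_side)
sheet_bg <- function(row) square_roi(row$bg_row0, row$bg_col0, row$bg_side)

stage_quantify <- function(config, manifest, out_dir) {
  if (is.null(manifest)) stop("'manifest' is required for the quantify stage")
  man <- check_manifest_files(manifest)
  px_nm <- config$pixel_size_nm %||% 83.3
  channels <- setdiff(manifest_channels(man), "membrane")
  meas <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    for (ch in channels) {
      img <- read_channel_tiff(row[[paste0("file_", ch)]], px_nm, ch)
      m <- measure_roi(img, sheet_roi(row), sheet_bg(row), row$sheet_id)
      meas[[length(meas) + 1L]] <- data.frame(
        sheet_id = row$sheet_id, construct = row$construct,
        condition = row$condition, treatment = row$treatment,
        replicate = row$replicate, channel = ch,
        mean_raw = m$mean_raw, mean_background = m$mean_background,
        mean_corrected = m$mean_corrected)
    }
  }
  meas <- do.call(rbind, meas)
  utils::write.csv(meas, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  # through-origin retention fit per construct: retained reporter vs
  # expression, when both channels are present
  fits <- NULL
  if (all(c("gfp", "ph") %in% channels)) {
    wide <- merge(
      meas[meas$channel == "gfp", c("sheet_id", "construct",
                                    "mean_corrected")],
      meas[meas$channel == "ph", c("sheet_id", "mean_corrected")],
      by = "sheet_id", suffixes = c("_gfp", "_ph"))
    fits <- do.call(rbind, lapply(split(wide, wide$construct), function(g) {
      f <- fit_through_origin(g$mean_corrected_gfp, g$mean_corrected_ph)
      data.frame(construct = g$construct[1], theta = f$theta,
                 r_squared = f$r_squared, n = f$n)
    }))
    rownames(fits) <- NULL
    utils::write.csv(fits, file.path(out_dir, "retention_fits.csv"),
                     row.names = FALSE)
  }
  list(measurements = meas, retention_fits = fits)
}

stage_coloc <- function(config, manifest, out_dir) {
  if (is.null(manifest)) stop("'manifest' is required for the coloc stage")
  man <- check_manifest_files(manifest)
  px_nm <- config$pixel_size_nm %||% 83.3
  pair <- config$channel_pair %||% c("gfp", "ph")
  block <- config$block_px %||% 4L
  nscr <- config$n_scrambles %||% 100L
  pthr <- config$p_threshold %||% 0.95
  rows <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    a <- read_channel_tiff(row[[paste0("file_", pair[1])]], px_nm, pair[1])
    b <- read_channel_tiff(row[[paste0("file_", pair[2])]], px_nm, pair[2])
    roi <- sheet_roi(row)
    pr <- pearson_roi(a, b, roi, row$sheet_id)
    ct <- costes_test(a, b, roi, block_px = block, n_scrambles = nscr,
                      seed = config$seed + i, p_threshold = pthr,
                      sheet_id = row$sheet_id)
    rows[[i]] <- data.frame(
      sheet_id = row$sheet_id, construct = row$construct,
      condition = row$condition, channel_a = pair[1], channel_b = pair[2],
      pcc = pr$pcc, costes_p = ct$p_value, keep = ct$keep)
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "coloc.csv"), row.names = FALSE)
  tab
}

stage_sted_nn <- function(config, out_dir) {
  px_nm <- config$pixel_size_nm %||% 25
  if (!is.null(config$red) && !is.null(config$longred)) {
    red <- read_channel_tiff(config$red, px_nm, "red")
    longred <- read_channel_tiff(config$longred, px_nm, "longred")
  } else {
    args <- utils::modifyList(
      list(preset = "sted", seed = config$seed),
      config$scene %||% list())
    sc <- do.call(simulate_scene, args)
    red <- sc$images$red
    longred <- sc$images$longred
  }
  ref_tol <- config$ref_tol %||% 2
  target_tol <- config$target_tol %||% 4
  common <- list(crosstalk_factor = config$crosstalk_factor %||% 0.5,
                 blur_sigma_px = config$blur_sigma_px %||% 0.5,
                 flip_axis = config$flip_axis %||% "h")
  if (isTRUE(config$sweep)) {
    sw <- do.call(tolerance_sweep, c(list(red, longred), common))
    tab <- summary(sw)
    utils::write.csv(tab, file.path(out_dir, "sted_nn_sweep.csv"),
                     row.names = FALSE)
    res <- sw[[1]]
  } else {
    res <- do.call(sted_nn, c(list(red, longred, ref_tol = ref_tol,
                                   target_tol = target_tol), common))
    tab <- summary(res)
    utils::write.csv(tab, file.path(out_dir, "sted_nn.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$clusters, file.path(out_dir, "sted_clusters.csv"),
                   row.names = FALSE)
  tab
}

#' Summarize measurements by group, with standard tests
#'
#' Tabulates mean, SD and n per group and runs the appropriate stock test:
#' a two-tailed unpaired t-test for two groups, one-way ANOVA for more
#' (followed by Dunnett contrasts against a named control when the
#' \pkg{multcomp} package is available). Groups with a single observation
#' get \code{NA} SD.
#'
#' @param data a data frame.
#' @param value name of the numeric measurement column.
#' @param group name of the grouping column.
#' @param control optional control group name for Dunnett contrasts.
#' @return A list of class \code{group_summary}: \code{summary} (group,
#'   n, mean, sd), \code{test} (test name), \code{p_value} (overall), and
#'   \code{comparisons} (per-contrast p-values, when computed).
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 5), y = c(1:5, 4:8))
#' summarize_groups(d, "y", "g")
#' @export
summarize_groups <- function(data, value, group, control = NULL) {
  data <- as.data.frame(data)
  y <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  tab <- do.call(rbind, lapply(levels(g), function(lv) {
    yi <- y[g == lv]
    data.frame(group = lv, n = length(yi), mean = mean(yi),
               sd = if (length(yi) > 1L) stats::sd(yi) else NA_real_)
  }))
  comparisons <- NULL
  if (any(tab$n < 2L)) {
    warning("group(s) with a single observation: no test performed")
    p <- NA_real_
    test <- "none (insufficient observations)"
  } else if (nlevels(g) == 2L) {
    sds <- tapply(y, g, stats::sd)
    if (any(sds == 0, na.rm = TRUE)) {
      warning("zero within-group variance: exact separation, p-value unreliable")
      p <- if (diff(tapply(y, g, mean)) == 0) 1 else NA_real_
      test <- "t-test (degenerate)"
    } else {
      p <- stats::t.test(y ~ g)$p.value
      test <- "Welch two-sample t-test"
    }
  } else {
    fit <- stats::aov(y ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    test <- "one-way ANOVA"
    if (!is.null(control) && requireNamespace("multcomp", quietly = TRUE)) {
      g2 <- stats::relevel(g, ref = control)
      fit2 <- stats::aov(y ~ g2)
      dt <- summary(multcomp::glht(fit2,
                                   linfct = multcomp::mcp(g2 = "Dunnett")))
      comparisons <- data.frame(
        contrast = names(dt$test$coefficients),
        estimate = unname(dt$test$coefficients),
        p_value = unname(dt$test$pvalues))
      test <- "one-way ANOVA + Dunnett"
    }
  }
  structure(list(summary = tab, test = test, p_value = p,
                 comparisons = comparisons),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat(sprintf("%s: p = %.4g\n", x$test, x$p_value))
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  invisible(x)
}
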