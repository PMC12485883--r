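#' Measure ROI intensity with background subtraction
#'
#' Computes the arithmetic mean intensity inside a square analysis ROI and
#' inside a background ROI placed next to the membrane, and their difference.
#' The corrected mean is deliberately not clipped at zero: clipping would
#' bias replicate averages for signals near background.
#'
#' @param image a \code{channel_image} or numeric matrix.
#' @param roi analysis \code{\link{square_roi}} (on the membrane).
#' @param background_roi background \code{\link{square_roi}} (off the
#'   membrane, same image).
#' @param sheet_id optional identifier carried into the result.
#' @return An object of class \code{roi_measurement} with \code{mean_raw},
#'   \code{mean_background} and \code{mean_corrected}
#'   (= \code{mean_raw - mean_background}).
#' @examples
#' img <- matrix(10, 32, 32); img[1:8, 1:8] <- 3
#' measure_roi(img, square_roi(16, 16, 8), square_roi(0, 0, 8))
#' @export
measure_roi <- function(image, roi, background_roi, sheet_id = "") {
  px <- img_pixels(image)
  check_roi_inside(roi, px, "analysis ROI")
  check_roi_inside(background_roi, px, "background ROI")
  if (rois_overlap(roi, background_roi))
    warning("analysis and background ROIs overlap")
  m_raw <- mean(roi_pixels(px, roi))
  m_bg <- mean(roi_pixels(px, background_roi))
  structure(list(
    mean_raw = m_raw, mean_background = m_bg,
    mean_corrected = m_raw - m_bg,
    channel_label = if (inherits(image, "channel_image"))
      image$channel_label else "",
    sheet_id = as.character(sheet_id)),
    class = "roi_measurement")
}

rois_overlap <- function(a, b) {
  a$row0 < b$row0 + b$side_px && b$row0 < a$row0 + a$side_px &&
    a$col0 < b$col0 + b$side_px && b$col0 < a$col0 + a$side_px
}

#' @export
print.roi_measurement <- function(x, ...) {
  cat(sprintf(
    "<roi_measurement%s> raw %.4g, background %.4g, corrected %.4g\n",
    if (nzchar(x$sheet_id)) paste0(" ", x$sheet_id) else "",
    x$mean_raw, x$mean_background, x$mean_corrected))
  invisible(x)
}

#' Normalize per-replicate measurements to a control construct
#'
#' For each biological replicate the test construct's value is expressed as
#' a percentage of the control construct measured in the same replicate
#' (control = 100\%). The mean percentage carries a two-sided 95\%
#' t-confidence interval (n - 1 degrees of freedom); the difference is
#' called significant when the interval excludes 100\%.
#'
#' @param values_by_replicate a data frame (or list coercible to one) with
#'   one row per replicate and numeric columns \code{control} and
#'   \code{test}, or a numeric vector of ready-made ratios in percent.
#' @param conf_level confidence level (fixed default 0.95).
#' @return An object of class \code{normalized_comparison}: \code{ratios_pct},
#'   \code{mean_pct}, \code{ci_low_pct}, \code{ci_high_pct},
#'   \code{significant}.
#' @examples
#' normalize_to_control(data.frame(control = c(10, 12, 11),
#'                                 test = c(6, 7, 7.5)))
#' @export
normalize_to_control <- function(values_by_replicate, conf_level = 0.95) {
  if (is.numeric(values_by_replicate) && is.null(dim(values_by_replicate))) {
    ratios <- as.numeric(values_by_replicate)
  } else {
    df <- as.data.frame(values_by_replicate)
    if (!all(c("control", "test") %in% names(df)))
      stop("'values_by_replicate' needs 'control' and 'test' columns")
    if (any(df$control <= 0))
      stop("all control values must be > 0")
    ratios <- 100 * df$test / df$control
  }
  n <- length(ratios)
  if (n < 2L)
    stop("at least 2 replicates are required for a confidence interval")
  m <- mean(ratios)
  se <- stats::sd(ratios) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  ci <- m + c(-1, 1) * tq * se
  structure(list(ratios_pct = ratios, mean_pct = m,
                 ci_low_pct = ci[1], ci_high_pct = ci[2],
                 conf_level = conf_level, n = n,
                 significant = ci[1] > 100 || ci[2] < 100),
            class = "normalized_comparison")
}

#' @export
print.normalized_comparison <- function(x, ...) {
  cat(sprintf(
    "<normalized_comparison> mean %.1f%% of control, %g%% CI [%.1f, %.1f], n = %d%s\n",
    x$mean_pct, 100 * x$conf_level, x$ci_low_pct, x$ci_high_pct, x$n,
    if (x$significant) " (CI excludes 100%: significant)"
    else " (not significant)"))
  invisible(x)
}

#' Linear regression through the origin
#'
#' Fits \eqn{y = \theta x} by least squares, the model used to compare how
#' much PIP2 reporter a patched construct retains per unit expression:
#' \eqn{\hat\theta = \sum x_i y_i / \sum x_i^2}. Two coefficients of
#' determination are computed: \code{r_squared} uses the centered total sum
#' of squares \eqn{1 - \sum(y-\hat\theta x)^2 / \sum(y-\bar y)^2} (the
#' value reported by common plotting software alongside origin-forced fits,
#' and the default here; it can be negative), and
#' \code{r_squared_uncentered} uses \eqn{\sum y^2} in the denominator.
#'
#' @param x numeric predictor (e.g. GFP expression intensity).
#' @param y numeric response (e.g. retained reporter intensity).
#' @return An object of class \code{origin_fit} with \code{theta},
#'   \code{r_squared}, \code{r_squared_uncentered} and \code{n}; supports
#'   \code{coef}, \code{predict}, \code{residuals}, \code{print} and
#'   \code{plot}.
#' @examples
#' fit <- fit_through_origin(1:10, 2 * (1:10))
#' coef(fit)
#' @export
fit_through_origin <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("at least 2 finite (x, y) pairs are required")
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  sxx <- sum(x^2)
  if (sxx <= 0) stop("sum(x^2) must be > 0 (all-zero x)")
  theta <- sum(x * y) / sxx
  res <- y - theta * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(theta = theta,
                 r_squared = 1 - ss_res / ss_tot,
                 r_squared_uncentered = 1 - ss_res / sum(y^2),
                 n = n, x = x, y = y, residuals = res),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("<origin_fit> theta = %.4g, R^2 = %.4g, n = %d\n",
              x$theta, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.origin_fit <- function(object, ...) c(theta = object$theta)

#' @export
predict.origin_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
  else if (is.list(newdata)) newdata$x else as.numeric(newdata)
  object$theta * x
}

#' @export
residuals.origin_fit <- function(object, ...) object$residuals

#' @export
plot.origin_fit <- function(x, xlab = "expression (a.u.)",
                            ylab = "retained reporter (a.u.)", ...) {
  plot(x$x, x$y, xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, x$theta)
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "theta = %.3g,  R² = %.3g", x$theta, x$r_squared))
  invisible(x)
}

#' Immunoprecipitation band ratio
#'
#' Relates the integrated density of the co-precipitated endogenous band to
#' the integrated density of the pulled-down GFP-construct band, and
#' normalizes the ratio to a control pull-down (control = 100\%).
#'
#' @param endo integrated density of the co-precipitated endogenous band.
#' @param gfp integrated density of the GFP bait band (> 0).
#' @param control_ratio endo/GFP ratio of the control construct (> 0).
#' @return An object of class \code{band_ratio} with \code{ratio}
#'   (= \code{endo / gfp}) and \code{ratio_normalized_pct}
#'   (= \code{100 * ratio / control_ratio}).
#' @examples
#' band_ratio(endo = 4, gfp = 2, control_ratio = 2)
#' @export
band_ratio <- function(endo, gfp, control_ratio) {
  if (!is.numeric(gfp) || any(gfp <= 0))
    stop("'gfp' integrated density must be > 0")
  if (!is.numeric(control_ratio) || any(control_ratio <= 0))
    stop("'control_ratio' must be > 0")
  r <- endo / gfp
  structure(list(endo_integrated = endo, gfp_integrated = gfp,
                 ratio = r, ratio_normalized_pct = 100 * r / control_ratio),
            class = "band_ratio")
}

#' @export
print.band_ratio <- function(x, ...) {
  cat(sprintf("<band_ratio> endo/GFP = %.4g (%.1f%% of control)\n",
              x$ratio, x$ratio_normalized_pct))
  invisible(x)
}
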