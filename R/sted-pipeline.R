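#' Two-color STED nano-cluster nearest-neighbor analysis
#'
#' Runs the full STED pipeline on a red (reference construct) and a
#' long-red (target construct) channel:
#' \enumerate{
#'   \item correct the long-red channel for crosstalk from the red channel
#'     (default 50\%);
#'   \item Gaussian-blur both channels (\eqn{\sigma} = 0.5 px) for noise
#'     reduction;
#'   \item detect local maxima in each channel with its noise tolerance;
#'   \item refine each reference maximum to sub-pixel precision (5-px
#'     center-of-mass disc) and classify it as a nano-cluster when at least
#'     one 31 x 3 linescan Gaussian fit has \eqn{R^2} above the threshold
#'     and its peak in the middle third;
#'   \item for every accepted reference nano-cluster, measure the distance
#'     (nm) to the nearest target-channel maximum (sub-pixel positions in
#'     both channels), and the same distance after mirroring the target
#'     positions (flipped-image control for the purely random distance).
#' }
#' Candidates whose refinement disc or linescan window would leave the
#' image are excluded before classification. Target maxima are not
#' classified; they are sub-pixel refined unless \code{refine_targets} is
#' \code{FALSE} (maxima too close to the border keep their pixel position).
#'
#' @param red,longred \code{channel_image}s (reference and target channel)
#'   of equal shape.
#' @param ref_tol,target_tol noise tolerances for maxima detection in the
#'   reference and target channel (paper-style pairs: 2/4, 4/8, 6/12,
#'   2/12).
#' @param roi optional \code{\link{square_roi}} restricting the analysis.
#' @param crosstalk_factor red-into-long-red bleed fraction to remove.
#' @param blur_sigma_px Gaussian blur width in px.
#' @param r2_threshold linescan fit-quality threshold.
#' @param flip_axis mirror axis for the random-distance control
#'   (\code{"h"} = left-right).
#' @param refine_targets sub-pixel refine target maxima too?
#' @param pixel_size_nm physical pixel size; defaults to the red channel's.
#' @return An object of class \code{nn_distance_set}: \code{distances_nm},
#'   \code{flipped_distances_nm}, \code{mean_nm}, \code{flipped_mean_nm},
#'   \code{tolerance_pair}, \code{clusters} (per-reference-candidate data
#'   frame with positions, fit parameters and the accepted flag),
#'   \code{target_positions}, counts and parameters.
#' @export
sted_nn <- function(red, longred, ref_tol = 2, target_tol = 4, roi = NULL,
                    crosstalk_factor = 0.5, blur_sigma_px = 0.5,
                    r2_threshold = 0.7, flip_axis = c("h", "v"),
                    refine_targets = TRUE, pixel_size_nm = NULL) {
  flip_axis <- match.arg(flip_axis)
  if (is.null(pixel_size_nm))
    pixel_size_nm <- if (inherits(red, "channel_image"))
      red$pixel_size_nm else 25
  red_px <- img_pixels(red)
  tgt_px <- correct_crosstalk(img_pixels(longred), red_px, crosstalk_factor)
  red_b <- gaussian_filter_matrix(red_px, blur_sigma_px)
  tgt_b <- gaussian_filter_matrix(tgt_px, blur_sigma_px)
  ref_max <- find_maxima(red_b, ref_tol, roi)
  tgt_max <- find_maxima(tgt_b, target_tol, roi)

  clusters <- characterize_references(red_b, ref_max, r2_threshold)
  acc <- clusters[clusters$accepted, , drop = FALSE]
  tgt_pos <- refine_positions(tgt_b, tgt_max, refine = refine_targets)

  d_obs <- d_flip <- numeric(0)
  if (nrow(acc) > 0L && nrow(tgt_pos) > 0L) {
    refpos <- cbind(acc$row_sub, acc$col_sub)
    d_obs <- nn_distances(refpos, tgt_pos, pixel_size_nm)
    flipped <- flip_control(tgt_pos, image_cols = ncol(red_px),
                            image_rows = nrow(red_px), axis = flip_axis)
    d_flip <- nn_distances(refpos, flipped, pixel_size_nm)
  }
  structure(list(
    distances_nm = d_obs, flipped_distances_nm = d_flip,
    mean_nm = if (length(d_obs)) mean(d_obs) else NA_real_,
    flipped_mean_nm = if (length(d_flip)) mean(d_flip) else NA_real_,
    tolerance_pair = c(ref_tol = ref_tol, target_tol = target_tol),
    pixel_size_nm = pixel_size_nm,
    clusters = clusters,
    target_positions = tgt_pos,
    n_ref_maxima = nrow(ref_max), n_ref_accepted = nrow(acc),
    n_target_maxima = nrow(tgt_max),
    params = list(crosstalk_factor = crosstalk_factor,
                  blur_sigma_px = blur_sigma_px,
                  r2_threshold = r2_threshold, flip_axis = flip_axis,
                  refine_targets = refine_targets)),
    class = "nn_distance_set")
}

# Sub-pixel refinement + linescan classification for reference maxima.
characterize_references <- function(img, maxima, r2_threshold) {
  n <- nrow(maxima)
  cols <- data.frame(row = integer(0), col = integer(0),
                     prominence = numeric(0),
                     row_sub = numeric(0), col_sub = numeric(0),
                     r2_h = numeric(0), center_h = numeric(0),
                     sigma_h = numeric(0),
                     r2_v = numeric(0), center_v = numeric(0),
                     sigma_v = numeric(0),
                     accepted = logical(0), excluded = logical(0))
  if (n == 0L) return(cols)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- maxima$row[i]; c <- maxima$col[i]
    rec <- tryCatch({
      sp <- refine_subpixel(img, r, c)
      fh <- linescan_fit(img, r, c, "horizontal")
      fv <- linescan_fit(img, r, c, "vertical")
      data.frame(row = r, col = c, prominence = maxima$prominence[i],
                 row_sub = sp[["row_sub"]], col_sub = sp[["col_sub"]],
                 r2_h = fh$r_squared, center_h = fh$center_px,
                 sigma_h = fh$sigma_px,
                 r2_v = fv$r_squared, center_v = fv$center_px,
                 sigma_v = fv$sigma_px,
                 accepted = classify_nanocluster(fh, fv, r2_threshold),
                 excluded = FALSE)
    }, sheetquant_candidate_excluded = function(e)
      data.frame(row = r, col = c, prominence = maxima$prominence[i],
                 row_sub = NA_real_, col_sub = NA_real_,
                 r2_h = NA_real_, center_h = NA_real_, sigma_h = NA_real_,
                 r2_v = NA_real_, center_v = NA_real_, sigma_v = NA_real_,
                 accepted = FALSE, excluded = TRUE))
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Sub-pixel (or pixel) positions for target maxima.
refine_positions <- function(img, maxima, refine = TRUE) {
  if (nrow(maxima) == 0L) return(matrix(numeric(0), 0, 2))
  pos <- cbind(as.numeric(maxima$row), as.numeric(maxima$col))
  if (!refine) return(pos)
  for (i in seq_len(nrow(pos))) {
    sp <- tryCatch(refine_subpixel(img, maxima$row[i], maxima$col[i]),
                   sheetquant_candidate_excluded = function(e) NULL)
    if (!is.null(sp)) pos[i, ] <- sp
  }
  pos
}

#' @export
print.nn_distance_set <- function(x, ...) {
  cat(sprintf(
    paste0("<nn_distance_set> tolerances %g/%g: %d/%d reference maxima ",
           "accepted, %d target maxima\n",
           "  observed mean NN %.1f nm, flipped control %.1f nm\n"),
    x$tolerance_pair[1], x$tolerance_pair[2],
    x$n_ref_accepted, x$n_ref_maxima, x$n_target_maxima,
    x$mean_nm, x$flipped_mean_nm))
  invisible(x)
}

#' @export
summary.nn_distance_set <- function(object, ...) {
  data.frame(ref_tol = object$tolerance_pair[[1]],
             target_tol = object$tolerance_pair[[2]],
             n_ref_accepted = object$n_ref_accepted,
             n_target_maxima = object$n_target_maxima,
             mean_observed_nm = object$mean_nm,
             mean_flipped_nm = object$flipped_mean_nm)
}

#' Noise-tolerance sweep of the STED nearest-neighbor analysis
#'
#' Re-runs \code{\link{sted_nn}} for a list of (reference, target) noise
#' tolerance pairs. Larger tolerances yield fewer maxima and hence larger
#' shortest distances; the sweep checks that a conclusion does not hinge on
#' one detection setting.
#'
#' @inheritParams sted_nn
#' @param pairs list of length-2 numeric vectors
#'   \code{c(ref_tol, target_tol)}; default the four settings
#'   (2,4), (4,8), (6,12), (2,12).
#' @param ... further arguments passed to \code{\link{sted_nn}}.
#' @return A list of class \code{tolerance_sweep} of
#'   \code{nn_distance_set}s; \code{summary()} tabulates them.
#' @export
tolerance_sweep <- function(red, longred,
                            pairs = list(c(2, 4), c(4, 8), c(6, 12),
                                         c(2, 12)),
                            ...) {
  if (length(pairs) == 0L) stop("'pairs' must be non-empty")
  out <- lapply(pairs, function(p)
    sted_nn(red, longred, ref_tol = p[[1]], target_tol = p[[2]], ...))
  class(out) <- "tolerance_sweep"
  out
}

#' @export
summary.tolerance_sweep <- function(object, ...) {
  do.call(rbind, lapply(unclass(object), summary.nn_distance_set))
}

#' @export
print.tolerance_sweep <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
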