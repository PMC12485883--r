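#' Pearson correlation between two channels in an ROI
#'
#' Standard Pearson correlation coefficient (PCC) over paired raw pixel
#' values inside the ROI, without background subtraction. The PCC is 1 for
#' perfectly overlapping images, 0 for unrelated images and -1 for an image
#' and its negative.
#'
#' @param a,b \code{channel_image}s (or matrices) of equal shape.
#' @param roi a \code{\link{square_roi}} inside both images.
#' @param sheet_id optional identifier carried into the result.
#' @return An object of class \code{pcc_result}: \code{pcc},
#'   \code{n_pixels}, \code{channel_pair}, \code{sheet_id}.
#' @examples
#' set.seed(1); m <- matrix(rnorm(64^2), 64, 64)
#' pearson_roi(m, 2 * m + 3, square_roi(0, 0, 64))$pcc
#' @export
pearson_roi <- function(a, b, roi, sheet_id = "") {
  pa <- img_pixels(a); pb <- img_pixels(b)
  if (!identical(dim(pa), dim(pb)))
    stop("channel images must have identical shapes")
  va <- as.vector(roi_pixels(pa, roi))
  vb <- as.vector(roi_pixels(pb, roi))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop(structure(class = c("sheetquant_zero_variance", "error",
                             "condition"),
                   list(message = "zero variance inside the ROI: PCC undefined",
                        call = sys.call(-1))))
  labs <- c(if (inherits(a, "channel_image")) a$channel_label else "a",
            if (inherits(b, "channel_image")) b$channel_label else "b")
  structure(list(pcc = stats::cor(va, vb), n_pixels = length(va),
                 channel_pair = labs, sheet_id = as.character(sheet_id)),
            class = "pcc_result")
}

#' @export
print.pcc_result <- function(x, ...) {
  cat(sprintf("<pcc_result%s> PCC(%s, %s) = %.4f over %d px\n",
              if (nzchar(x$sheet_id)) paste0(" ", x$sheet_id) else "",
              x$channel_pair[1], x$channel_pair[2], x$pcc, x$n_pixels))
  invisible(x)
}

#' Costes block-scramble significance test for a PCC
#'
#' Validates an observed PCC by comparing it with the PCC distribution
#' obtained after scrambling channel \code{b} (the reporter/mCherry channel;
#' channel \code{a} stays fixed) in PSF-sized square pixel blocks. The ROI
#' is cropped to the largest multiple of \code{block_px} (bottom/right
#' trimmed) so the observed and scrambled PCCs share an identical support;
#' blocks are then permuted uniformly at random \code{n_scrambles} times.
#' The Costes P-value is the fraction of scrambled PCCs strictly below the
#' observed PCC (ties count as not-below, which is conservative toward
#' exclusion); the observed PCC is kept when \code{p_value >= p_threshold}.
#'
#' @inheritParams pearson_roi
#' @param block_px scramble block edge in pixels; the default 4 matches a
#'   PSF size of 4 pixels at 83.3 nm/px.
#' @param n_scrambles number of random block permutations (>= 20).
#' @param seed integer RNG seed (or \code{NULL} for the current RNG state).
#' @param p_threshold keep threshold on the Costes P-value.
#' @return An object of class \code{costes_result}: \code{observed_pcc},
#'   \code{scrambled_pcc} (vector), \code{n_scrambles}, \code{n_below},
#'   \code{p_value}, \code{block_px}, \code{keep}.
#' @export
costes_test <- function(a, b, roi, block_px = 4L, n_scrambles = 100L,
                        seed = NULL, p_threshold = 0.95, sheet_id = "") {
  if (n_scrambles < 20L)
    stop("'n_scrambles' must be at least 20")
  if (block_px < 1L || block_px != round(block_px))
    stop("'block_px' must be a positive integer")
  if (roi$side_px < block_px)
    stop("ROI side must be at least one block")
  side <- (roi$side_px %/% block_px) * block_px
  croi <- square_roi(roi$row0, roi$col0, side)
  va <- as.vector(roi_pixels(img_pixels(a), croi))
  mb <- roi_pixels(img_pixels(b), croi)
  vb <- as.vector(mb)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop(structure(class = c("sheetquant_zero_variance", "error",
                             "condition"),
                   list(message = "zero variance inside the ROI: PCC undefined",
                        call = sys.call(-1))))
  observed <- stats::cor(va, vb)
  k <- side %/% block_px                  # tiles per edge
  # linear pixel indices of each tile, in a fixed tile order
  tile_idx <- vector("list", k * k)
  t0 <- 1L
  for (tc in 0:(k - 1L)) for (tr in 0:(k - 1L)) {
    rows <- (tr * block_px + 1L):(tr * block_px + block_px)
    cols <- (tc * block_px + 1L):(tc * block_px + block_px)
    tile_idx[[t0]] <- as.vector(outer(rows, (cols - 1L) * side, "+"))
    t0 <- t0 + 1L
  }
  dest <- unlist(tile_idx)
  scrambled <- with_seed(seed, vapply(seq_len(n_scrambles), function(i) {
    perm <- sample.int(k * k)
    sb <- vb
    sb[dest] <- vb[unlist(tile_idx[perm])]
    stats::cor(va, sb)
  }, numeric(1)))
  n_below <- sum(scrambled < observed)
  p <- n_below / n_scrambles
  structure(list(observed_pcc = observed, scrambled_pcc = scrambled,
                 n_scrambles = as.integer(n_scrambles),
                 n_below = as.integer(n_below), p_value = p,
                 block_px = as.integer(block_px),
                 p_threshold = p_threshold,
                 keep = p >= p_threshold,
                 sheet_id = as.character(sheet_id)),
            class = "costes_result")
}

#' @export
print.costes_result <- function(x, ...) {
  cat(sprintf(
    "<costes_result%s> PCC %.4f, P = %.3f (%d/%d scrambles below), block %d px: %s\n",
    if (nzchar(x$sheet_id)) paste0(" ", x$sheet_id) else "",
    x$observed_pcc, x$p_value, x$n_below, x$n_scrambles, x$block_px,
    if (x$keep) "keep" else "exclude"))
  invisible(x)
}

#' Filter PCC values by their Costes validation
#'
#' Keeps only the PCC results whose Costes P-value reached the keep
#' threshold (P >= 0.95 by default in \code{\link{costes_test}}), preserving
#' input order, and reports how many were excluded.
#'
#' @param pcc_results list of \code{pcc_result}s.
#' @param costes_results list of matching \code{costes_result}s (same
#'   length and order).
#' @param quiet suppress the exclusion-count message?
#' @return The kept subset of \code{pcc_results}.
#' @export
filter_by_costes <- function(pcc_results, costes_results, quiet = FALSE) {
  if (length(pcc_results) != length(costes_results))
    stop("'pcc_results' and 'costes_results' must have equal length")
  keep <- vapply(costes_results, function(cr) isTRUE(cr$keep), logical(1))
  if (!quiet && any(!keep))
    message(sum(!keep), " of ", length(keep),
            " PCC values excluded by the Costes test")
  pcc_results[keep]
}
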