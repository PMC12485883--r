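#' Correct spectral crosstalk
#'
#' Removes bleed-through of the red channel into the long-red channel:
#' \code{longred - factor * red}, clipped at zero (negative photon counts
#' are unphysical and destabilize the center-of-mass refinement). The
#' default factor 0.5 corresponds to 50\% red-into-long-red crosstalk.
#'
#' @param longred,red \code{channel_image}s or matrices of equal shape.
#' @param factor crosstalk fraction in \code{[0, 1)}.
#' @return Same type as \code{longred}.
#' @export
correct_crosstalk <- function(longred, red, factor = 0.5) {
  if (!is.numeric(factor) || factor < 0 || factor >= 1)
    stop("'factor' must lie in [0, 1)")
  p <- img_pixels(longred); b <- img_pixels(red)
  if (!identical(dim(p), dim(b)))
    stop("'longred' and 'red' must have identical shapes")
  out <- pmax(p - factor * b, 0)
  if (inherits(longred, "channel_image")) {
    longred$pixels <- out
    longred
  } else out
}

# 8-neighbor offsets (row, col)
.nb8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
              dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

#' Detect local maxima with a noise-tolerance (prominence) criterion
#'
#' ImageJ-compatible "Find maxima": candidate peaks are processed in
#' descending intensity order and each one grows a region over 8-connected
#' pixels whose value is within \code{noise_tolerance} of the peak value.
#' If, before descending more than the tolerance from its own peak, the
#' region reaches higher terrain or territory already claimed by a higher
#' peak, the candidate is merged away; otherwise it is reported as a
#' maximum. Equal-valued plateaus count as one candidate located at the
#' plateau pixel closest to the plateau centroid (lexicographic (row, col)
#' on exact ties).
#'
#' @param image a \code{channel_image} or numeric matrix.
#' @param noise_tolerance positive prominence threshold: a maximum must
#'   stand more than this far above the saddle connecting it to higher
#'   terrain.
#' @param roi optional \code{\link{square_roi}}; maxima are detected inside
#'   it and reported in full-image 0-based pixel coordinates.
#' @return A data frame of class \code{maximum_candidates} with columns
#'   \code{row}, \code{col} (0-based integers), \code{value} and
#'   \code{prominence} (value drop to the highest exterior saddle;
#'   \code{Inf} for the global maximum), ordered by decreasing value.
#' @examples
#' m <- matrix(0, 16, 16); m[5, 5] <- 10; m[12, 12] <- 8
#' find_maxima(m, noise_tolerance = 4)
#' @export
find_maxima <- function(image, noise_tolerance, roi = NULL) {
  if (!is.numeric(noise_tolerance) || noise_tolerance <= 0)
    stop("'noise_tolerance' must be > 0")
  px <- img_pixels(image)
  off <- c(0L, 0L)
  if (!is.null(roi)) {
    px <- roi_pixels(px, roi)
    off <- c(roi$row0, roi$col0)
  }
  nr <- nrow(px); nc <- ncol(px)
  if (nr < 1L || nc < 1L || length(px) == 0L) stop("empty ROI")
  plateaus <- find_plateau_maxima(px)
  if (length(plateaus) == 0L)
    return(empty_maxima(off))
  vals <- vapply(plateaus, function(p) p$value, numeric(1))
  cent <- t(vapply(plateaus, function(p) p$centroid_px, numeric(2)))
  ord <- order(-vals, cent[, 1], cent[, 2])
  owner <- matrix(FALSE, nr, nc)
  out <- list()
  for (pi in ord) {
    pl <- plateaus[[pi]]
    v <- pl$value
    if (any(owner[pl$members])) next       # absorbed by a higher region
    res <- flood_region(px, pl$members, v - noise_tolerance, v, owner)
    if (res$merged) next
    owner[res$region] <- TRUE
    out[[length(out) + 1L]] <- c(pl$centroid_px, v, res$prominence)
  }
  if (length(out) == 0L) return(empty_maxima(off))
  m <- do.call(rbind, out)
  df <- data.frame(row = as.integer(m[, 1] - 1L + off[1]),
                   col = as.integer(m[, 2] - 1L + off[2]),
                   value = m[, 3], prominence = m[, 4])
  df <- df[order(-df$value, df$row, df$col), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("maximum_candidates", "data.frame")
  df
}

empty_maxima <- function(off) {
  df <- data.frame(row = integer(0), col = integer(0),
                   value = numeric(0), prominence = numeric(0))
  class(df) <- c("maximum_candidates", "data.frame")
  df
}

# Equal-valued plateau maxima: connected components of equal value in which
# no pixel has a strictly higher 8-neighbor. Returns, per plateau, the
# linear member indices, the value and the representative pixel (member
# closest to the plateau centroid, lexicographic tie-break), 1-based.
find_plateau_maxima <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  # pixels with no strictly higher neighbor
  mx <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(.nb8))) {
    dr <- .nb8[k, 1]; dc <- .nb8[k, 2]
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    sub <- mx[rs - dr, cs - dc, drop = FALSE]
    mx[rs - dr, cs - dc] <- pmax(sub, px[rs, cs, drop = FALSE])
  }
  cand <- which(px >= mx)
  visited <- matrix(FALSE, nr, nc)
  plateaus <- list()
  for (s in cand) {
    if (visited[s]) next
    v <- px[s]
    # flood the equal-value plateau containing s (may include pixels with a
    # higher neighbor, which invalidates the whole plateau)
    queue <- s; visited[s] <- TRUE
    members <- integer(0)
    ok <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue <- queue[-length(queue)]
      members <- c(members, p)
      if (px[p] < mx[p]) ok <- FALSE   # plateau touches higher terrain
      pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
      for (k in seq_len(8L)) {
        qr <- pr + .nb8[k, 1]; qc <- pc + .nb8[k, 2]
        if (qr < 1L || qr > nr || qc < 1L || qc > nc) next
        q <- qr + (qc - 1L) * nr
        if (!visited[q] && px[q] == v) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
    if (!ok) next
    if (length(members) == nr * nc) next  # flat ROI: zero prominence
    rr <- (members - 1L) %% nr + 1L
    cc <- (members - 1L) %/% nr + 1L
    d2 <- (rr - mean(rr))^2 + (cc - mean(cc))^2
    best <- which(d2 == min(d2))
    best <- best[order(rr[best], cc[best])][1L]
    plateaus[[length(plateaus) + 1L]] <-
      list(members = members, value = v,
           centroid_px = c(rr[best], cc[best]))
  }
  plateaus
}

# Grow an 8-connected region from 'seeds' over pixels with value >= floor.
# Reports merged = TRUE as soon as the region reaches a pixel with value
# strictly above 'peak' or a pixel already owned by a higher maximum.
# Otherwise returns the full region and the prominence (peak minus the
# highest pixel adjacent to, but outside, the region).
flood_region <- function(px, seeds, floor_val, peak, owner) {
  nr <- nrow(px); nc <- ncol(px)
  inreg <- matrix(FALSE, nr, nc)
  inreg[seeds] <- TRUE
  queue <- seeds
  region <- integer(0)
  best_out <- -Inf
  while (length(queue)) {
    p <- queue[[length(queue)]]; queue <- queue[-length(queue)]
    region <- c(region, p)
    pr <- (p - 1L) %% nr + 1L; pc <- (p - 1L) %/% nr + 1L
    for (k in seq_len(8L)) {
      qr <- pr + .nb8[k, 1]; qc <- pc + .nb8[k, 2]
      if (qr < 1L || qr > nr || qc < 1L || qc > nc) next
      q <- qr + (qc - 1L) * nr
      if (inreg[q]) next
      vq <- px[q]
      if (vq >= floor_val) {
        if (vq > peak || owner[q])
          return(list(merged = TRUE))
        inreg[q] <- TRUE
        queue <- c(queue, q)
      } else if (vq > best_out) best_out <- vq
    }
  }
  list(merged = FALSE, region = region, prominence = peak - best_out)
}

#' Sub-pixel refinement by center of mass
#'
#' Places a circular ROI (default diameter 5 px) on a detected maximum and
#' returns the intensity-weighted centroid over the pixels whose centers
#' lie within the disc, yielding a sub-pixel position.
#'
#' @param image a \code{channel_image} or matrix.
#' @param row,col 0-based integer pixel position of the maximum.
#' @param diameter_px disc diameter in pixels.
#' @return Numeric vector \code{c(row_sub, col_sub)} (0-based continuous).
#'   Errors with condition class \code{sheetquant_candidate_excluded} when
#'   the disc does not fit inside the image; falls back to the integer
#'   position (with a warning) when the disc holds no positive intensity.
#' @export
refine_subpixel <- function(image, row, col, diameter_px = 5L) {
  px <- img_pixels(image)
  rad <- diameter_px / 2
  ri <- as.integer(round(rad - 0.5))   # integer offset extent
  if (row - ri < 0 || col - ri < 0 ||
      row + ri > nrow(px) - 1L || col + ri > ncol(px) - 1L)
    stop(structure(class = c("sheetquant_candidate_excluded", "error",
                             "condition"),
                   list(message = "center-of-mass disc leaves the image",
                        call = sys.call(-1))))
  offs <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2, ]
  w <- px[cbind(row + offs$dr + 1L, col + offs$dc + 1L)]
  tot <- sum(w)
  if (tot <= 0) {
    warning("no positive intensity in the disc; using the pixel position")
    return(c(row_sub = as.numeric(row), col_sub = as.numeric(col)))
  }
  c(row_sub = row + sum(w * offs$dr) / tot,
    col_sub = col + sum(w * offs$dc) / tot)
}

#' Gaussian linescan fit at a maximum
#'
#' Places a 31 x 3 px linescan (horizontal or vertical) centered on a
#' maximum, averages across the 3-px width, and fits
#' \eqn{A e^{-(x-\mu)^2 / 2\sigma^2} + b} by nonlinear least squares
#' (Levenberg-Marquardt, \eqn{\sigma} bounded to \code{[0.5, 31]} px).
#' The fit is characterized by the centered \eqn{R^2} and by whether the
#' fitted peak lies in the middle third of the scan
#' (\eqn{\mu \in [31/3, 62/3]} in 0-based linescan coordinates).
#'
#' @inheritParams refine_subpixel
#' @param orientation \code{"horizontal"} (scan along columns) or
#'   \code{"vertical"} (along rows).
#' @param length_px,width_px linescan dimensions (odd; defaults 31 and 3).
#' @return An object of class \code{linescan_fit}: \code{orientation},
#'   \code{profile}, \code{amplitude}, \code{center_px}, \code{sigma_px},
#'   \code{offset}, \code{r_squared} (\code{-Inf} if the fit failed) and
#'   \code{peak_in_middle_third}.
#' @export
linescan_fit <- function(image, row, col,
                         orientation = c("horizontal", "vertical"),
                         length_px = 31L, width_px = 3L) {
  orientation <- match.arg(orientation)
  px <- img_pixels(image)
  hl <- length_px %/% 2L; hw <- width_px %/% 2L
  if (orientation == "horizontal") {
    rlo <- row - hw; rhi <- row + hw; clo <- col - hl; chi <- col + hl
  } else {
    rlo <- row - hl; rhi <- row + hl; clo <- col - hw; chi <- col + hw
  }
  if (rlo < 0 || clo < 0 || rhi > nrow(px) - 1L || chi > ncol(px) - 1L)
    stop(structure(class = c("sheetquant_candidate_excluded", "error",
                             "condition"),
                   list(message = "linescan window leaves the image",
                        call = sys.call(-1))))
  win <- px[(rlo + 1L):(rhi + 1L), (clo + 1L):(chi + 1L), drop = FALSE]
  profile <- if (orientation == "horizontal") colMeans(win) else rowMeans(win)
  x <- seq_along(profile) - 1
  fit <- fit_gaussian_profile(x, profile, length_px)
  mid <- c(length_px / 3, 2 * length_px / 3)
  structure(list(orientation = orientation, profile = as.numeric(profile),
                 amplitude = fit$A, center_px = fit$mu,
                 sigma_px = fit$sigma, offset = fit$b,
                 r_squared = fit$r2,
                 peak_in_middle_third = is.finite(fit$mu) &&
                   fit$mu >= mid[1] && fit$mu <= mid[2]),
            class = "linescan_fit")
}

fit_gaussian_profile <- function(x, y, length_px) {
  start <- list(A = max(y) - min(y), mu = x[which.max(y)], sigma = 2,
                b = min(y))
  if (start$A <= 0) start$A <- max(abs(y), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)) + b,
      start = start,
      lower = c(A = 0, mu = -length_px, sigma = 0.5, b = -Inf),
      upper = c(A = Inf, mu = 2 * length_px, sigma = length_px, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A = NA_real_, mu = NA_real_, sigma = NA_real_,
                b = NA_real_, r2 = -Inf))
  p <- stats::coef(fit)
  res <- y - stats::predict(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else -Inf
  list(A = unname(p["A"]), mu = unname(p["mu"]),
       sigma = unname(p["sigma"]), b = unname(p["b"]), r2 = r2)
}

#' @export
print.linescan_fit <- function(x, ...) {
  cat(sprintf(
    "<linescan_fit %s> A %.3g, mu %.2f px, sigma %.2f px, R^2 %.3f%s\n",
    x$orientation, x$amplitude, x$center_px, x$sigma_px, x$r_squared,
    if (x$peak_in_middle_third) ", peak in middle third" else ""))
  invisible(x)
}

#' Classify a maximum as a nano-cluster
#'
#' A detected maximum is rated a well-defined nano-cluster when at least
#' one of its two linescans (horizontal or vertical) has both a Gaussian
#' fit quality above the threshold and its fitted peak in the middle third
#' of the scan — the conjunction is evaluated per linescan.
#'
#' @param horizontal,vertical \code{linescan_fit}s at the maximum.
#' @param r2_threshold fit-quality threshold (default 0.7).
#' @return Logical: accepted as nano-cluster?
#' @export
classify_nanocluster <- function(horizontal, vertical, r2_threshold = 0.7) {
  passes <- function(f)
    is.finite(f$r_squared) && f$r_squared > r2_threshold &&
      isTRUE(f$peak_in_middle_third)
  passes(horizontal) || passes(vertical)
}

#' Nearest-neighbor distances between two point sets
#'
#' For each reference position, the Euclidean distance (in nm) to the
#' nearest target position.
#'
#' @param reference,targets matrices with columns (row, col) of 0-based
#'   sub-pixel positions; \code{targets} must be non-empty.
#' @param pixel_size_nm physical pixel size (25 nm for STED).
#' @return Numeric vector of distances in nm, one per reference row.
#' @examples
#' nn_distances(cbind(0, 0), cbind(3, 4), pixel_size_nm = 25) # 125 nm
#' @export
nn_distances <- function(reference, targets, pixel_size_nm = 25) {
  reference <- as_position_matrix(reference)
  targets <- as_position_matrix(targets)
  if (nrow(targets) == 0L) stop("'targets' must be non-empty")
  if (nrow(reference) == 0L) return(numeric(0))
  out <- numeric(nrow(reference))
  chunk <- max(1L, floor(2e6 / nrow(targets)))
  for (s in seq(1L, nrow(reference), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(reference))
    d2 <- outer(reference[s:e, 1], targets[, 1], "-")^2 +
      outer(reference[s:e, 2], targets[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out * pixel_size_nm
}

as_position_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(c("row_sub", "col_sub"), names(x))
    if (length(cols) == 2L) x <- x[, cols] else x <- x[, c("row", "col")]
  }
  m <- as.matrix(x)
  if (length(m) == 0L) return(matrix(numeric(0), 0, 2))
  if (ncol(m) != 2L) stop("positions must have two columns (row, col)")
  storage.mode(m) <- "double"
  m
}

#' Mirror target positions for the random-distance control
#'
#' Flips positions across the image midline so that nearest-neighbor
#' distances recomputed against the unchanged reference positions sample
#' the purely random distance expected for spatially unrelated point
#' patterns. The default is a left-right mirror
#' (\code{col -> (image_cols - 1) - col}); \code{axis = "v"} mirrors
#' top-bottom instead.
#'
#' @param targets matrix of 0-based (row, col) sub-pixel positions.
#' @param image_cols,image_rows image extent in pixels along the mirrored
#'   axis.
#' @param axis \code{"h"} (left-right flip) or \code{"v"} (top-bottom).
#' @return Matrix of flipped positions, same shape and order.
#' @export
flip_control <- function(targets, image_cols = NULL, image_rows = NULL,
                         axis = c("h", "v")) {
  axis <- match.arg(axis)
  m <- as_position_matrix(targets)
  if (axis == "h") {
    if (is.null(image_cols)) stop("'image_cols' is required for axis 'h'")
    m[, 2] <- (image_cols - 1) - m[, 2]
  } else {
    if (is.null(image_rows)) stop("'image_rows' is required for axis 'v'")
    m[, 1] <- (image_rows - 1) - m[, 1]
  }
  m
}
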