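#' Generate a lipid-domain field
#'
#' Produces a smooth, non-negative random field standing in for the spatial
#' pattern of a PIP2-rich inner-leaflet lipid domain, as reported by a
#' fluorescent PH-domain probe. White Gaussian noise is smoothed with an
#' isotropic Gaussian kernel and passed through a soft logistic threshold so
#' that a fraction \code{enriched_fraction} of the membrane forms contiguous
#' "rich" areas; the result is normalized to mean 1 so that it can be used
#' directly as a relative density.
#'
#' The smoothing bandwidth is \code{correlation_length_px / 2}, which places
#' the autocorrelation of the pre-threshold field at \code{1/e} at lag
#' \code{correlation_length_px}.
#'
#' @param shape integer vector \code{c(rows, cols)}, both at least 32.
#' @param correlation_length_px spatial correlation length in pixels (>= 1).
#' @param enriched_fraction fraction of pixels in the enriched phase,
#'   strictly between 0 and 1.
#' @param seed integer RNG seed, or \code{NULL} to draw from the current
#'   RNG state.
#' @return An object of class \code{domain_field} with elements
#'   \code{values} (rows x cols matrix, mean exactly 1),
#'   \code{correlation_length_px} and \code{enriched_fraction}.
#' @examples
#' dom <- generate_domain_field(c(64, 64), 6, 0.3, seed = 1)
#' mean(dom$values)
#' @export
generate_domain_field <- function(shape, correlation_length_px,
                                  enriched_fraction, seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L))
    stop("'shape' must be c(rows, cols) with both dimensions >= 32")
  if (!is.numeric(correlation_length_px) || correlation_length_px < 1)
    stop("'correlation_length_px' must be >= 1")
  if (enriched_fraction <= 0 || enriched_fraction >= 1)
    stop("'enriched_fraction' must lie strictly between 0 and 1")
  with_seed(seed, {
    z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    z <- gaussian_filter_matrix(z, correlation_length_px / 2)
    z <- (z - mean(z)) / stats::sd(z)
    q <- stats::quantile(z, 1 - enriched_fraction, names = FALSE)
    f <- stats::plogis((z - q) / 0.25)
    f <- f / mean(f)
    structure(list(values = f,
                   correlation_length_px = correlation_length_px,
                   enriched_fraction = enriched_fraction),
              class = "domain_field")
  })
}

#' @export
print.domain_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<domain_field> %d x %d px, correlation length %g px, enriched fraction %g\n",
    d[1], d[2], x$correlation_length_px, x$enriched_fraction))
  invisible(x)
}

#' Place nano-cluster emitters with domain affinity
#'
#' Draws cluster centers with probability proportional to
#' \code{domain$values ^ affinity}: \code{affinity = 0} gives complete
#' spatial randomness, larger values concentrate clusters in domain-rich
#' areas (a stronger preference for PIP2-rich membrane). Centers are
#' continuous (uniform sub-pixel jitter inside the chosen pixel); the number
#' of fluorophore copies per cluster is a shifted Poisson
#' \code{1 + Poisson(copies_mean - 1)} so every cluster holds at least one
#' copy.
#'
#' @param domain a \code{domain_field}.
#' @param n_clusters number of clusters (>= 1).
#' @param affinity non-negative placement weighting exponent.
#' @param copies_mean mean copies per cluster (>= 1).
#' @param channel_label label attached to the resulting channel.
#' @param mask optional 0/1 matrix (same shape as the domain) restricting
#'   placement, e.g. a membrane footprint.
#' @inheritParams generate_domain_field
#' @return An object of class \code{emitter_set}: \code{centers} (n x 2
#'   matrix of 0-based continuous (row, col) positions), \code{copies}
#'   (integer vector), \code{shape}, \code{affinity}, \code{channel_label}.
#' @export
place_emitters <- function(domain, n_clusters, affinity = 0, copies_mean = 1,
                           channel_label = "", mask = NULL, seed = NULL) {
  stopifnot(inherits(domain, "domain_field"))
  if (n_clusters < 1 || n_clusters != round(n_clusters))
    stop("'n_clusters' must be a positive integer")
  if (!is.numeric(affinity) || affinity < 0)
    stop("'affinity' must be >= 0")
  if (copies_mean < 1) stop("'copies_mean' must be >= 1")
  d <- dim(domain$values)
  with_seed(seed, {
    w <- as.vector(domain$values) ^ affinity
    if (!is.null(mask)) {
      if (!identical(dim(mask), d))
        stop("'mask' must match the domain dimensions")
      w <- w * as.vector(mask)
    }
    pix <- sample.int(prod(d), n_clusters, replace = TRUE, prob = w)
    r0 <- (pix - 1L) %% d[1]          # 0-based row of sampled pixel
    c0 <- (pix - 1L) %/% d[1]         # 0-based col
    rows <- pmin(pmax(r0 + stats::runif(n_clusters, -0.5, 0.5), 0), d[1] - 1)
    cols <- pmin(pmax(c0 + stats::runif(n_clusters, -0.5, 0.5), 0), d[2] - 1)
    copies <- 1L + stats::rpois(n_clusters, max(copies_mean - 1, 0))
    structure(list(centers = cbind(row = rows, col = cols),
                   copies = as.integer(copies),
                   shape = d, affinity = affinity,
                   channel_label = as.character(channel_label)),
              class = "emitter_set")
  })
}

#' @export
print.emitter_set <- function(x, ...) {
  cat(sprintf(
    "<emitter_set '%s'> %d clusters (%d copies total), affinity %g, %d x %d px\n",
    x$channel_label, nrow(x$centers), sum(x$copies), x$affinity,
    x$shape[1], x$shape[2]))
  invisible(x)
}

#' Rendering parameters
#'
#' @param psf_sigma_nm Gaussian point-spread standard deviation in nm.
#' @param pixel_size_nm physical pixel size in nm (83.3 epi, 25 STED).
#' @param photons_per_emitter expected photons per fluorophore copy.
#' @param background_level expected background photons per pixel.
#' @param shot_noise apply Poisson shot noise? (\code{FALSE} renders the
#'   noiseless expectation image).
#' @param seed RNG seed for the shot noise, or \code{NULL}.
#' @return A list of class \code{render_params}.
#' @export
render_params <- function(psf_sigma_nm, pixel_size_nm,
                          photons_per_emitter = 1000,
                          background_level = 0,
                          shot_noise = TRUE, seed = NULL) {
  stopifnot(psf_sigma_nm > 0, pixel_size_nm > 0, photons_per_emitter > 0,
            background_level >= 0)
  structure(list(psf_sigma_nm = psf_sigma_nm, pixel_size_nm = pixel_size_nm,
                 photons_per_emitter = photons_per_emitter,
                 background_level = background_level,
                 shot_noise = isTRUE(shot_noise), seed = seed),
            class = "render_params")
}

# Expected-intensity image from point sources: each source i deposits
# amplitude[i] photons integrated over pixel areas (error-function profile),
# so total flux is conserved exactly for sources away from the borders.
render_spots <- function(centers, amplitudes, sigma_px, shape,
                         background = 0) {
  lam <- matrix(background, shape[1], shape[2])
  if (is.null(centers) || nrow(centers) == 0L) return(lam)
  r <- ceiling(6 * sigma_px) + 1L
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    rows <- max(0L, floor(r0) - r):min(shape[1] - 1L, ceiling(r0) + r)
    cols <- max(0L, floor(c0) - r):min(shape[2] - 1L, ceiling(c0) + r)
    wr <- stats::pnorm(rows + 0.5, r0, sigma_px) -
      stats::pnorm(rows - 0.5, r0, sigma_px)
    wc <- stats::pnorm(cols + 0.5, c0, sigma_px) -
      stats::pnorm(cols - 0.5, c0, sigma_px)
    lam[rows + 1L, cols + 1L] <- lam[rows + 1L, cols + 1L] +
      amplitudes[i] * outer(wr, wc)
  }
  lam
}

#' Render a channel image from an emitter set
#'
#' Sums isotropic Gaussian spots (pixel-integrated, so flux is conserved for
#' interior spots) of width \code{psf_sigma_nm / pixel_size_nm} pixels over a
#' constant background, then applies Poisson shot noise unless
#' \code{params$shot_noise} is \code{FALSE}. All copies of a cluster sit at
#' the cluster center; the cluster is a point source of
#' \code{copies * photons_per_emitter} photons.
#'
#' @param emitters an \code{emitter_set}.
#' @param params a \code{render_params}.
#' @return A \code{channel_image}.
#' @export
render_channel <- function(emitters, params) {
  stopifnot(inherits(emitters, "emitter_set"),
            inherits(params, "render_params"))
  sigma_px <- params$psf_sigma_nm / params$pixel_size_nm
  lam <- render_spots(emitters$centers,
                      emitters$copies * params$photons_per_emitter,
                      sigma_px, emitters$shape, params$background_level)
  px <- if (params$shot_noise) {
    with_seed(params$seed,
              matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam)))
  } else lam
  channel_image(px, params$pixel_size_nm, emitters$channel_label)
}

#' Mix spectral crosstalk into a channel
#'
#' Adds \code{factor} times the bleed source to the primary channel,
#' creating the bleed-through artifact that \code{\link{correct_crosstalk}}
#' removes (50\% red-into-long-red bleed in the two-color STED setup).
#'
#' @param primary,bleed_source \code{channel_image}s or matrices of equal
#'   shape.
#' @param factor bleed fraction in \code{[0, 1)}.
#' @return Same type as \code{primary}.
#' @export
apply_crosstalk <- function(primary, bleed_source, factor) {
  if (!is.numeric(factor) || factor < 0 || factor >= 1)
    stop("'factor' must lie in [0, 1)")
  p <- img_pixels(primary); b <- img_pixels(bleed_source)
  if (!identical(dim(p), dim(b)))
    stop("'primary' and 'bleed_source' must have identical shapes")
  out <- p + factor * b
  if (inherits(primary, "channel_image")) {
    primary$pixels <- out
    primary
  } else out
}

#' Simulate a synthetic membrane-sheet scene
#'
#' Generates a complete multi-channel scene with known ground truth, for one
#' of two imaging presets:
#' \describe{
#'   \item{\code{"epi"}}{83.3 nm pixels. Channels: \code{membrane} (flat
#'     marker field), \code{gfp} (nano-clustered construct placed with
#'     \code{affinity} for the lipid domain) and \code{ph} (smooth
#'     PH-reporter field proportional to the domain). Under
#'     \code{condition = "aGFP"} (antibody patching) the \code{ph} channel
#'     additionally contains reporter trapped under each cluster in
#'     proportion to the local domain value, emulating retention of the
#'     PIP2 probe by patched clusters.}
#'   \item{\code{"sted"}}{25 nm pixels. Channels: \code{red} (reference
#'     construct) and \code{longred} (target construct, with
#'     \code{crosstalk_factor} of the red channel mixed in, as acquired).
#'     A fraction \code{shared_fraction} of the target cluster centers
#'     coincides with reference centers, emulating mixed nano-clusters.}
#' }
#'
#' @param preset \code{"epi"} or \code{"sted"}.
#' @param shape image dimensions \code{c(rows, cols)}.
#' @param seed integer seed; the whole scene is reproducible from it.
#' @param n_clusters clusters in the (reference) clustered channel.
#' @param affinity domain-placement affinity of the clustered channel(s).
#' @param copies_mean mean fluorophore copies per cluster.
#' @param correlation_length_px,enriched_fraction domain-field parameters.
#' @param photons_per_emitter,background_level,psf_sigma_nm rendering
#'   parameters (preset defaults if \code{NULL}).
#' @param condition epi only: \code{"directly_fixed"} or \code{"aGFP"}.
#' @param ph_gain epi only: expected PH photons per pixel per unit domain.
#' @param retention_gain epi only: trapped-reporter photons per construct
#'   photon (aGFP condition).
#' @param ph_residual_frac epi only: fraction of the free reporter signal
#'   surviving the rinse in the aGFP condition.
#' @param membrane_margin_frac epi only: margin (fraction of each image
#'   dimension) around the central membrane footprint; outside it only the
#'   camera background remains.
#' @param target_n_clusters,shared_fraction sted only: clusters in the
#'   target channel and the fraction of them sharing reference centers.
#' @param crosstalk_factor sted only: red-into-long-red bleed fraction.
#' @param shot_noise apply Poisson noise?
#' @return An object of class \code{synthetic_scene}: \code{domain},
#'   \code{emitters} (list per channel), \code{images} (list of
#'   \code{channel_image}), \code{params}.
#' @examples
#' sc <- simulate_scene("epi", shape = c(64, 64), n_clusters = 40, seed = 1)
#' names(sc$images)
#' @export
simulate_scene <- function(preset = c("epi", "sted"), shape = c(256, 256),
                           seed = NULL,
                           n_clusters = 150, affinity = 1, copies_mean = 4,
                           correlation_length_px = NULL,
                           enriched_fraction = 0.3,
                           photons_per_emitter = NULL,
                           background_level = NULL, psf_sigma_nm = NULL,
                           condition = c("aGFP", "directly_fixed"),
                           ph_gain = 200, retention_gain = 1,
                           ph_residual_frac = 0.05,
                           membrane_margin_frac = 0.15,
                           target_n_clusters = n_clusters,
                           shared_fraction = 0, crosstalk_factor = 0.5,
                           shot_noise = TRUE) {
  preset <- match.arg(preset)
  condition <- match.arg(condition)
  pixel_size_nm <- if (preset == "epi") 83.3 else 25
  if (is.null(correlation_length_px))
    correlation_length_px <- if (preset == "epi") 6 else 20
  if (is.null(photons_per_emitter))
    photons_per_emitter <- if (preset == "epi") 300 else 1000
  if (is.null(background_level))
    background_level <- if (preset == "epi") 20 else 5
  if (is.null(psf_sigma_nm))
    psf_sigma_nm <- if (preset == "epi") 110 else 40
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("'shared_fraction' must lie in [0, 1]")
  params <- list(preset = preset, shape = as.integer(shape), seed = seed,
                 pixel_size_nm = pixel_size_nm, n_clusters = n_clusters,
                 affinity = affinity, copies_mean = copies_mean,
                 correlation_length_px = correlation_length_px,
                 enriched_fraction = enriched_fraction,
                 photons_per_emitter = photons_per_emitter,
                 background_level = background_level,
                 psf_sigma_nm = psf_sigma_nm, condition = condition,
                 ph_gain = ph_gain, retention_gain = retention_gain,
                 ph_residual_frac = ph_residual_frac,
                 membrane_margin_frac = membrane_margin_frac,
                 target_n_clusters = target_n_clusters,
                 shared_fraction = shared_fraction,
                 crosstalk_factor = crosstalk_factor,
                 shot_noise = shot_noise)
  with_seed(seed, {
    dom <- generate_domain_field(shape, correlation_length_px,
                                 enriched_fraction)
    sigma_px <- psf_sigma_nm / pixel_size_nm
    rp <- render_params(psf_sigma_nm, pixel_size_nm, photons_per_emitter,
                        background_level, shot_noise = FALSE)
    noisify <- function(lam, label) {
      px <- if (shot_noise)
        matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
      else lam
      channel_image(px, pixel_size_nm, label)
    }
    if (preset == "epi") {
      # membrane sheet occupies a central footprint; outside it only camera
      # background remains, so background ROIs "next to the membrane" see
      # no signal, as in the real assay
      mrow <- round(membrane_margin_frac * shape[1])
      mcol <- round(membrane_margin_frac * shape[2])
      mask <- matrix(0, shape[1], shape[2])
      mask[(mrow + 1L):(shape[1] - mrow), (mcol + 1L):(shape[2] - mcol)] <- 1
      em <- place_emitters(dom, n_clusters, affinity, copies_mean,
                           channel_label = "gfp", mask = mask)
      lam_gfp <- render_spots(em$centers, em$copies * photons_per_emitter,
                              sigma_px, em$shape) + background_level
      domval <- dom$values[cbind(floor(em$centers[, 1] + 0.5) + 1L,
                                 floor(em$centers[, 2] + 0.5) + 1L)]
      if (condition == "directly_fixed") {
        # free reporter decorates the full PIP2 pattern
        lam_ph <- ph_gain * dom$values * mask + background_level
      } else {
        # after patching and rinsing, only a residual of the free reporter
        # remains; the rest of the retained signal sits under the patched
        # clusters, in proportion to the local domain value
        lam_ph <- ph_residual_frac * ph_gain * dom$values * mask +
          background_level +
          render_spots(em$centers,
                       retention_gain * photons_per_emitter *
                         em$copies * domval,
                       1.5 * sigma_px, em$shape)
      }
      lam_mem <- 500 * mask + background_level
      structure(list(
        domain = dom,
        emitters = list(gfp = em),
        membrane_mask = mask,
        images = list(membrane = noisify(lam_mem, "membrane"),
                      gfp = noisify(lam_gfp, "gfp"),
                      ph = noisify(lam_ph, "ph")),
        params = params), class = "synthetic_scene")
    } else {
      ref <- place_emitters(dom, n_clusters, affinity, copies_mean,
                            channel_label = "red")
      n_shared <- round(shared_fraction * target_n_clusters)
      tgt <- place_emitters(dom, target_n_clusters, affinity, copies_mean,
                            channel_label = "longred")
      if (n_shared > 0) {
        take <- sample.int(nrow(ref$centers), n_shared, replace = TRUE)
        tgt$centers[seq_len(n_shared), ] <- ref$centers[take, ]
      }
      lam_red <- render_spots(ref$centers, ref$copies * photons_per_emitter,
                              sigma_px, ref$shape, background_level)
      lam_tgt <- render_spots(tgt$centers, tgt$copies * photons_per_emitter,
                              sigma_px, tgt$shape, background_level)
      red <- noisify(lam_red, "red")
      longred <- noisify(lam_tgt, "longred")
      longred <- apply_crosstalk(longred, red, crosstalk_factor)
      structure(list(
        domain = dom,
        emitters = list(red = ref, longred = tgt),
        images = list(red = red, longred = longred),
        params = params), class = "synthetic_scene")
    }
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> preset '%s', %d x %d px, channels: %s\n",
              x$params$preset, x$params$shape[1], x$params$shape[2],
              paste(names(x$images), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Writes one 16-bit grayscale TIFF per channel, a ground-truth table
#' (\code{truth.csv}: channel, cluster_id, row_px, col_px, copies) and the
#' generation parameters (\code{params.yaml}).
#'
#' @param scene a \code{synthetic_scene}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(scene$images))
    write_channel_tiff(scene$images[[ch]], file.path(dir, paste0(ch, ".tif")))
  truth <- do.call(rbind, lapply(names(scene$emitters), function(ch) {
    em <- scene$emitters[[ch]]
    data.frame(channel = ch, cluster_id = seq_len(nrow(em$centers)),
               row_px = em$centers[, 1], col_px = em$centers[, 2],
               copies = em$copies)
  }))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(scene$params, file.path(dir, "params.yaml"))
  invisible(dir)
}
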