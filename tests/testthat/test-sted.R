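# a noiseless rendered spot image for localization tests
spot_image <- function(r0, c0, shape = c(21, 21), photons = 1500,
                       sigma_px = 1.6, background = 0) {
  sheetquant:::render_spots(cbind(r0, c0), photons, sigma_px, shape,
                            background)
}

test_that("crosstalk correction inverts the mixing and clips at zero", {
  set.seed(101)
  red <- matrix(rpois(400, 40), 20, 20)
  expect_true(all(correct_crosstalk(0.5 * red, red, 0.5) == 0))
  lr <- matrix(rpois(400, 30), 20, 20)
  expect_identical(correct_crosstalk(lr, red, 0), lr + 0)
  mixed <- apply_crosstalk(lr, red, 0.5)
  expect_equal(correct_crosstalk(mixed, red, 0.5), lr + 0)
  # clipping: correction never goes negative
  expect_true(all(correct_crosstalk(lr * 0, red, 0.5) == 0))
  expect_error(correct_crosstalk(lr[1:5, ], red, 0.5), "shape")
})

test_that("Gaussian blur conserves mass and matches the kernel oracle", {
  expect_equal(blur(matrix(3, 15, 15), 0.5), matrix(3, 15, 15),
               tolerance = 1e-12)
  # central impulse: center value equals the discrete kernel central weight
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  for (s in c(0.5, 1, 2)) {
    b <- blur(imp, s)
    expect_equal(b[11, 11], direct_gauss_center_weight(s), tolerance = 0.01)
    expect_equal(sum(b), 1, tolerance = 1e-3) # interior content
  }
  # arbitrary interior-supported image
  m <- matrix(0, 41, 41)
  m[15:27, 15:27] <- matrix(runif(169, 0, 10), 13, 13)
  expect_equal(sum(blur(m, 1.5)), sum(m), tolerance = 1e-3)
  expect_error(blur(m, 0), "positive")
})

test_that("find_maxima handles single spots, plateaus and flat images", {
  # single Gaussian spot of amplitude 10 on a flat background
  m <- 2 + 10 * exp(-(outer((1:31 - 16)^2, (1:31 - 12)^2, "+")) / 8)
  fm <- find_maxima(m, 4)
  expect_equal(nrow(fm), 1)
  expect_equal(c(fm$row, fm$col), c(15, 11)) # 0-based

  # flat image: no maxima at any tolerance
  expect_equal(nrow(find_maxima(matrix(5, 16, 16), 0.1)), 0)

  # two peaks with prominences 3 and 5 above the saddle, tolerance 4:
  # only the higher survives
  m2 <- matrix(0, 16, 16)
  m2[4, 4] <- 10          # peak A
  m2[12, 12] <- 8         # peak B, saddle path at 5 between them
  m2[8, 8] <- 5
  m2[5:7, 5:7] <- 5; m2[9:11, 9:11] <- 5
  fm2 <- find_maxima(m2, 4)
  expect_equal(nrow(fm2), 1)
  expect_equal(c(fm2$row, fm2$col), c(3, 3))

  # plateau: 2x2 flat top reported once at the centroid pixel
  m3 <- matrix(0, 16, 16)
  m3[7:8, 9:10] <- 6
  fm3 <- find_maxima(m3, 2)
  expect_equal(nrow(fm3), 1)
  expect_equal(c(fm3$row, fm3$col), c(6, 8)) # top-left of the 2x2, 0-based

  expect_error(find_maxima(m3, 0), "> 0")
})

test_that("find_maxima agrees with the exhaustive prominence oracle", {
  set.seed(111)
  for (i in 1:60) {
    px <- matrix(sample(0:9, 256, replace = TRUE), 16, 16)
    for (tol in c(1, 2, 4)) {
      got <- find_maxima(px, tol)
      want <- oracle_find_maxima(px, tol)
      expect_identical(position_key(cbind(got$row, got$col)),
                       position_key(want),
                       label = sprintf("image %d, tolerance %d", i, tol))
    }
  }
})

test_that("maxima counts are non-increasing in the noise tolerance", {
  set.seed(112)
  for (i in 1:10) {
    px <- matrix(rpois(1024, 20), 32, 32)
    counts <- vapply(c(1, 2, 4, 8, 16), function(tol)
      nrow(find_maxima(px, tol)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("center-of-mass refinement is exact and unbiased", {
  # perfectly symmetric spot centered on a pixel: integer position
  sym <- spot_image(10, 10)
  sp <- refine_subpixel(sym, 10, 10)
  expect_equal(unname(sp), c(10, 10), tolerance = 1e-9)

  # hand-computed centroid on explicit weights
  m <- matrix(0, 11, 11)
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  offs <- offs[offs$dr^2 + offs$dc^2 <= 6.25, ]
  w <- seq_len(nrow(offs))
  m[cbind(5 + offs$dr + 1, 5 + offs$dc + 1)] <- w
  sp2 <- refine_subpixel(m, 5, 5)
  expect_equal(unname(sp2),
               c(5 + sum(w * offs$dr) / sum(w),
                 5 + sum(w * offs$dc) / sum(w)), tolerance = 1e-12)

  # ground-truth sub-pixel offset recovered within 0.1 px (noiseless,
  # compact spot; for wide spots the truncated disc shrinks the recovered
  # offset toward the pixel center, see the RMSE/bias test below)
  off <- spot_image(10.3, 9.8, sigma_px = 1.0)
  sp3 <- refine_subpixel(off, 10, 10)
  expect_lt(abs(sp3[["row_sub"]] - 10.3), 0.1)
  expect_lt(abs(sp3[["col_sub"]] - 9.8), 0.1)

  # disc leaving the image is a candidate-excluded signal
  expect_error(refine_subpixel(sym, 1, 10),
               class = "sheetquant_candidate_excluded")
  # all-zero disc: warning and integer fallback
  expect_warning(sp4 <- refine_subpixel(matrix(0, 11, 11), 5, 5),
                 "pixel position")
  expect_equal(unname(sp4), c(5, 5))
})

test_that("linescan Gaussian fits classify centered peaks only", {
  # noiseless Gaussian centered on the candidate: peak at scan position 15
  img <- spot_image(20, 20, shape = c(41, 41), sigma_px = 2)
  fh <- linescan_fit(img, 20, 20, "horizontal")
  expect_gt(fh$r_squared, 0.999)
  expect_equal(fh$center_px, 15, tolerance = 0.05)
  expect_true(fh$peak_in_middle_third)
  fv <- linescan_fit(img, 20, 20, "vertical")
  expect_true(fv$peak_in_middle_third)
  expect_true(classify_nanocluster(fh, fv))

  # spot 12 px off-center: fits well but peaks outside the middle third
  img2 <- spot_image(20, 8, shape = c(41, 41), sigma_px = 2)
  f2 <- linescan_fit(img2, 20, 20, "horizontal")
  expect_equal(f2$center_px, 3, tolerance = 0.2)
  expect_false(f2$peak_in_middle_third)

  # linescan window leaving the image is a candidate-excluded signal
  expect_error(linescan_fit(img, 20, 5, "horizontal"),
               class = "sheetquant_candidate_excluded")
})

test_that("a linear ramp is rejected by the middle-third rule", {
  # a Gaussian flank can track a pure ramp closely (the best fit may reach
  # a high R^2), but its fitted peak always sits outside the scan's middle
  # third, so the per-linescan conjunction rejects it
  ramp <- matrix(rep(0:40, each = 41), 41, 41)
  f <- linescan_fit(ramp, 20, 20, "horizontal")
  expect_false(f$peak_in_middle_third)
  fv <- linescan_fit(ramp, 20, 20, "vertical") # constant profile
  expect_false(isTRUE(fv$r_squared > 0.7) && isTRUE(fv$peak_in_middle_third))
  expect_false(classify_nanocluster(f, fv))
})

test_that("classification requires R^2 and centering on the same linescan", {
  mk <- function(r2, center) structure(
    list(r_squared = r2, center_px = center,
         peak_in_middle_third = center >= 31 / 3 && center <= 62 / 3),
    class = "linescan_fit")
  expect_true(classify_nanocluster(mk(0.9, 15), mk(0.2, 3)))  # H passes
  expect_false(classify_nanocluster(mk(0.9, 25), mk(0.5, 15))) # split
  expect_false(classify_nanocluster(mk(0.3, 15), mk(0.5, 16))) # both fail
  expect_false(classify_nanocluster(mk(-Inf, NaN), mk(-Inf, NaN)))
})

test_that("nearest-neighbor distances are Euclidean in nm", {
  expect_equal(nn_distances(cbind(0, 0), cbind(3, 4), 25), 125)
  expect_equal(nn_distances(cbind(2, 2), rbind(c(2, 2), c(9, 9)), 25), 0)
  expect_error(nn_distances(cbind(0, 0), matrix(numeric(0), 0, 2)),
               "non-empty")
  # nearest of several targets
  refs <- rbind(c(0, 0), c(10, 10))
  tg <- rbind(c(0, 1), c(10, 14), c(12, 10))
  expect_equal(nn_distances(refs, tg, 25), c(25, 50))
})

test_that("flipping is an involution that preserves central columns", {
  set.seed(121)
  pos <- cbind(runif(50, 0, 63), runif(50, 0, 63))
  f1 <- flip_control(pos, image_cols = 64)
  expect_equal(flip_control(f1, image_cols = 64), pos, tolerance = 1e-12)
  center <- cbind(5, 31.5)
  expect_equal(flip_control(center, image_cols = 64)[, 2], 31.5)
  fv <- flip_control(pos, image_rows = 64, axis = "v")
  expect_equal(fv[, 2], pos[, 2])
  expect_equal(fv[, 1], 63 - pos[, 1])
  expect_error(flip_control(pos, axis = "h"), "image_cols")
})

test_that("the full STED pipeline is deterministic and sweeps sensibly", {
  sc <- simulate_scene("sted", shape = c(128, 128), n_clusters = 40,
                       shared_fraction = 0.5, seed = 131)
  r1 <- sted_nn(sc$images$red, sc$images$longred)
  r2 <- sted_nn(sc$images$red, sc$images$longred)
  expect_identical(r1$distances_nm, r2$distances_nm)
  expect_identical(r1$flipped_distances_nm, r2$flipped_distances_nm)
  expect_identical(r1$clusters, r2$clusters)
  expect_s3_class(summary(r1), "data.frame")

  # higher tolerances detect fewer or equal maxima in each channel
  sw <- tolerance_sweep(sc$images$red, sc$images$longred,
                        pairs = list(c(2, 4), c(4, 8), c(6, 12)))
  tab <- summary(sw)
  expect_true(all(diff(tab$n_target_maxima) <= 0))
  nref <- vapply(unclass(sw), function(x) x$n_ref_maxima, numeric(1))
  expect_true(all(diff(nref) <= 0))
  # with the reference set held fixed, fewer target maxima cannot shorten
  # the nearest-neighbor distances (subset property)
  sw2 <- tolerance_sweep(sc$images$red, sc$images$longred,
                         pairs = list(c(2, 4), c(2, 8), c(2, 12)))
  tab2 <- summary(sw2)
  expect_true(all(diff(tab2$mean_observed_nm) >= 0))
  expect_true(all(diff(tab2$mean_flipped_nm) >= 0))
  expect_error(tolerance_sweep(sc$images$red, sc$images$longred,
                               pairs = list()), "non-empty")
})
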