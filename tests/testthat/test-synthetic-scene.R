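# autocorrelation of a field at integer lag along rows
row_autocorr <- function(m, lag) {
  n <- ncol(m)
  cor(as.vector(m[, 1:(n - lag)]), as.vector(m[, (lag + 1):n]))
}

test_that("domain field is mean-normalized, deterministic and validated", {
  dom <- generate_domain_field(c(64, 64), 6, 0.3, seed = 11)
  expect_equal(mean(dom$values), 1, tolerance = 1e-9)
  expect_true(all(dom$values >= 0) && all(is.finite(dom$values)))
  dom2 <- generate_domain_field(c(64, 64), 6, 0.3, seed = 11)
  expect_identical(dom$values, dom2$values)
  expect_error(generate_domain_field(c(16, 64), 6, 0.3, seed = 1), ">= 32")
  expect_error(generate_domain_field(c(64, 64), 0.5, 0.3, seed = 1), ">= 1")
  expect_error(generate_domain_field(c(64, 64), 6, 1.2, seed = 1),
               "between 0 and 1")
})

test_that("domain autocorrelation decays and scales with correlation length", {
  for (s in 1:3) {
    d8 <- generate_domain_field(c(96, 96), 8, 0.3, seed = s)
    d2 <- generate_domain_field(c(96, 96), 2, 0.3, seed = s)
    # longer correlation length -> more correlation left at lag 4
    expect_gt(row_autocorr(d8$values, 4), row_autocorr(d2$values, 4))
    # autocorrelation at lag = correlation length below lag-1 value
    expect_lt(row_autocorr(d8$values, 8), row_autocorr(d8$values, 1))
  }
})

test_that("emitter placement is CSR at affinity 0 and domain-biased above", {
  dom <- generate_domain_field(c(64, 64), 6, 0.3, seed = 21)
  domval_at <- function(em)
    dom$values[cbind(floor(em$centers[, 1] + 0.5) + 1,
                     floor(em$centers[, 2] + 0.5) + 1)]
  em0 <- place_emitters(dom, 1e4, affinity = 0, seed = 1)
  v0 <- domval_at(em0)
  se <- sd(dom$values) / sqrt(length(v0))
  expect_lt(abs(mean(v0) - 1), 3 * se)

  # single cluster, in bounds
  em1 <- place_emitters(dom, 1, affinity = 1, seed = 2)
  expect_equal(nrow(em1$centers), 1)
  expect_true(all(em1$centers >= 0) &&
                all(em1$centers[, 1] <= 63) && all(em1$centers[, 2] <= 63))
  expect_error(place_emitters(dom, 10, affinity = -1, seed = 1), ">= 0")
  expect_error(place_emitters(dom, 0, seed = 1), "positive integer")
})

test_that("mean domain value at centers is monotone in affinity", {
  affs <- c(0, 0.5, 1, 2)
  means <- matrix(NA_real_, 20, length(affs))
  for (s in 1:20) {
    dom <- generate_domain_field(c(64, 64), 6, 0.3, seed = 100 + s)
    for (k in seq_along(affs)) {
      em <- place_emitters(dom, 500, affinity = affs[k], seed = 200 + s)
      means[s, k] <- mean(
        dom$values[cbind(floor(em$centers[, 1] + 0.5) + 1,
                         floor(em$centers[, 2] + 0.5) + 1)])
    }
  }
  avg <- colMeans(means)
  expect_true(all(diff(avg) > 0))
  # per-seed monotonicity of the stronger contrasts
  expect_true(all(means[, 4] > means[, 1]))
})

test_that("rendering conserves flux and places spots correctly", {
  # empty emitter set, zero background, no noise -> all-zero image
  empty <- structure(list(centers = matrix(numeric(0), 0, 2),
                          copies = integer(0), shape = c(32L, 32L),
                          affinity = 0, channel_label = "x"),
                     class = "emitter_set")
  rp0 <- render_params(100, 25, 1000, 0, shot_noise = FALSE)
  img0 <- render_channel(empty, rp0)
  expect_true(all(img0$pixels == 0))

  # one emitter at the grid center, noiseless: max at that pixel,
  # flux within 1%
  one <- structure(list(centers = cbind(16, 16), copies = 1L,
                        shape = c(33L, 33L), affinity = 0,
                        channel_label = "x"),
                   class = "emitter_set")
  img1 <- render_channel(one, render_params(40, 25, 1000, 0,
                                            shot_noise = FALSE))
  expect_equal(which.max(img1$pixels), 16 * 33 + 17) # pixel (17,17) 1-based
  expect_equal(sum(img1$pixels), 1000, tolerance = 0.01)

  # interior spots: total = background*npx + photons*emitters within 1%
  dom <- generate_domain_field(c(64, 64), 6, 0.3, seed = 31)
  em <- place_emitters(dom, 30, affinity = 0, copies_mean = 3, seed = 32)
  # push centers into the interior (>= 4 sigma from borders)
  em$centers <- 12 + (em$centers / 63) * 39
  rp <- render_params(40, 25, 500, 2, shot_noise = FALSE)
  img <- render_channel(em, rp)
  expect_equal(sum(img$pixels), 2 * 64 * 64 + 500 * sum(em$copies),
               tolerance = 0.01)

  # determinism of the noisy render
  rpn <- render_params(40, 25, 500, 2, shot_noise = TRUE, seed = 7)
  expect_identical(render_channel(em, rpn)$pixels,
                   render_channel(em, rpn)$pixels)
})

test_that("same-center channels colocalize strongly", {
  dom <- generate_domain_field(c(96, 96), 6, 0.3, seed = 41)
  em <- place_emitters(dom, 80, affinity = 1, copies_mean = 3, seed = 42)
  rp <- render_params(110, 83.3, 300, 0, shot_noise = FALSE)
  a <- render_channel(em, rp)
  b <- render_channel(em, rp)
  pcc <- pearson_roi(a, b, square_roi(0, 0, 96))$pcc
  expect_gt(pcc, 0.8)
})

test_that("crosstalk mixing is exact and invertible", {
  set.seed(51)
  p <- matrix(rpois(400, 30), 20, 20)
  b <- matrix(rpois(400, 50), 20, 20)
  expect_identical(apply_crosstalk(p, b, 0), p + 0)
  expect_equal(apply_crosstalk(p * 0, b, 0.5), 0.5 * b)
  mixed <- apply_crosstalk(p, b, 0.5)
  expect_equal(correct_crosstalk(mixed, b, 0.5), p + 0)
  expect_error(apply_crosstalk(p, b[1:10, ], 0.5), "shape")
  expect_error(apply_crosstalk(p, b, 1), "\\[0, 1\\)")
})

test_that("scenes regenerate bit-identically and write complete output", {
  sc1 <- simulate_scene("sted", shape = c(64, 64), n_clusters = 20,
                        seed = 61)
  sc2 <- simulate_scene("sted", shape = c(64, 64), n_clusters = 20,
                        seed = 61)
  expect_identical(sc1$images$red$pixels, sc2$images$red$pixels)
  expect_identical(sc1$images$longred$pixels, sc2$images$longred$pixels)
  expect_identical(sc1$emitters$red$centers, sc2$emitters$red$centers)

  dir <- withr::local_tempdir()
  write_scene(sc1, dir)
  expect_true(all(file.exists(file.path(
    dir, c("red.tif", "longred.tif", "truth.csv", "params.yaml")))))
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_setequal(unique(truth$channel), c("red", "longred"))
  expect_equal(nrow(truth[truth$channel == "red", ]), 20)
  # TIFF round-trip preserves integer photon counts
  back <- read_channel_tiff(file.path(dir, "red.tif"), 25, "red")
  expect_equal(back$pixels, sc1$images$red$pixels)
})
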