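test_that("linearization subtracts black, floors, normalizes and balances", {
  counts <- matrix(512, 6, 6)
  counts[1, 1] <- 65535     # R site under RGGB
  counts[1, 2] <- 65535     # G site
  counts[3, 1] <- 100       # below the black level
  cfa <- cfa_image(counts, "RGGB", black_level = 512, white_level = 65535,
                   wb_gains = c(r = 2, b = 0.5))
  lin <- linearize(cfa)
  expect_equal(lin$data[1, 2], 1.0)        # G untouched by gains
  expect_equal(lin$data[1, 1], 2.0)        # R scaled by its gain
  expect_equal(lin$data[3, 1], 0)          # clipped at black
  expect_true(lin$normalized)
  expect_error(linearize(lin), "already")

  # all pixels at black -> all zeros
  z <- linearize(cfa_image(matrix(512, 6, 6), "RGGB", 512, 65535))
  expect_true(all(z$data == 0))
})

test_that("linearization is monotone in counts within each site class", {
  set.seed(21)
  a <- matrix(sample(0:65535, 64), 8, 8)
  b <- pmin(a + sample(0:500, 64, replace = TRUE), 65535)
  la <- linearize(cfa_image(a, "GRBG", 512, 65535, wb_gains = c(r = 1.7, b = 1.4)))
  lb <- linearize(cfa_image(b, "GRBG", 512, 65535, wb_gains = c(r = 1.7, b = 1.4)))
  expect_true(all(lb$data >= la$data))
})

test_that("demosaicing is exact on constants and planar ramps", {
  for (pattern in c("RGGB", "BGGR", "GRBG", "GBRG")) {
    const <- demosaic_mhc(matrix(0.37, 10, 12), pattern)
    expect_equal(max(abs(const$data - 0.37)), 0, tolerance = 1e-12)
  }
  set.seed(5)
  for (k in 1:5) {
    abc <- runif(3, -0.2, 0.2)
    ramp <- outer(1:16, 1:20, function(y, x) 0.4 + abc[1] * x / 20 + abc[2] * y / 16)
    out <- demosaic_mhc(ramp, "RGGB")$data
    interior <- out[3:14, 3:18, ]
    truth <- array(ramp[3:14, 3:18], dim = dim(interior))
    expect_equal(max(abs(interior - truth)), 0, tolerance = 1e-12)
  }
})

test_that("demosaicing equals the direct-convolution oracle", {
  set.seed(6)
  for (pattern in c("RGGB", "BGGR", "GRBG", "GBRG")) {
    x <- matrix(runif(16 * 16), 16, 16)
    expect_equal(demosaic_mhc(x, pattern)$data, demosaic_oracle(x, pattern),
                 tolerance = 1e-14)
  }
  expect_error(demosaic_mhc(matrix(0.5, 4, 4), "RGGB"), "5 x 5")
})

test_that("camera-space conversion is a plain matrix map", {
  img <- array(runif(60), dim = c(4, 5, 3))
  expect_equal(camera_to_rgb(img, diag(3))$data, img)
  one <- array(c(0.2, 0.3, 0.4), dim = c(1, 1, 3))
  expect_equal(as.numeric(camera_to_rgb(one, diag(c(2, 1, 1)))$data),
               c(0.4, 0.3, 0.4))
  set.seed(7)
  M <- diag(3) + matrix(runif(9, -0.2, 0.2), 3)
  back <- camera_to_rgb(camera_to_rgb(img, M), solve(M))
  expect_equal(back$data, img, tolerance = 1e-12)
  expect_error(camera_to_rgb(img, matrix(1, 3, 3)), "singular")
})

test_that("chart measurement recovers rendered patch colors", {
  sc <- render_scene(n_leaves = 0, seed = 13)
  chart <- sc$truth$chart
  measured <- measure_chart(sc$image, chart$corners)
  expect_lt(max(abs(measured - chart$patch_colors)), 1 / 255)

  # reversed corner order scrambles patch identity: residual must inflate
  good <- fit_affine_color_map(measured, chart$patch_colors)$fit_residual
  rev_meas <- measure_chart(sc$image, chart$corners[c(3, 4, 1, 2), ])
  bad <- fit_affine_color_map(rev_meas, chart$patch_colors)$fit_residual
  expect_gt(bad, 100 * max(good, 1e-6))

  expect_error(measure_chart(sc$image, matrix(c(1, 1, 50, 50, 99, 99, 50, 50),
                                              4, 2, byrow = TRUE)),
               "collinear|degenerate")
  expect_error(measure_chart(sc$image, chart$corners + 1e4), "outside")
})

test_that("patch medians shrug off salt-and-pepper contamination", {
  sc <- render_scene(n_leaves = 0, seed = 14)
  img <- sc$image
  set.seed(14)
  # corrupt 10% of each patch's central pixels with 0/1 salt and pepper
  clean <- measure_chart(img, sc$truth$chart$corners)
  idx <- which(array(runif(length(img)) < 0.10, dim = dim(img)))
  img[idx] <- rep(c(0, 1), length.out = length(idx))
  noisy <- measure_chart(img, sc$truth$chart$corners)
  expect_lt(max(abs(noisy - clean)), 0.02)
})

test_that("affine color fit matches its closed-form cases and the normal equations", {
  ref <- make_reference_chart()$patch_colors
  id <- fit_affine_color_map(ref, ref)
  expect_equal(id$M, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(id$b, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(id$fit_residual, 0, tolerance = 1e-12)

  half <- fit_affine_color_map(0.5 * ref + 0.1, ref)
  expect_equal(half$M, 2 * diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(half$b, rep(-0.2, 3), tolerance = 1e-9)

  set.seed(31)
  Mstar <- diag(3) + matrix(runif(9, -0.1, 0.1), 3)
  bstar <- runif(3, -0.05, 0.05)
  measured <- t(Mstar %*% t(ref)) + rep(bstar, each = 24) +
    matrix(rnorm(72, 0, 1e-6), 24, 3)
  fit <- fit_affine_color_map(measured, ref)
  beta <- affine_fit_oracle(measured, ref)
  expect_equal(fit$M, t(beta[1:3, ]), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$b, as.numeric(beta[4, ]), tolerance = 1e-8)

  expect_error(fit_affine_color_map(matrix(0.5, 24, 3), ref), "rank-deficient")
})

test_that("the fitted map beats random affine competitors in residual", {
  set.seed(32)
  ref <- make_reference_chart()$patch_colors
  measured <- ref + matrix(rnorm(72, 0, 0.02), 24, 3)
  fit <- fit_affine_color_map(measured, ref)
  sse <- function(M, b) sum((t(M %*% t(measured)) +
                               rep(b, each = 24) - ref)^2)
  for (k in 1:20) {
    M <- fit$M + matrix(rnorm(9, 0, 0.01), 3)
    b <- fit$b + rnorm(3, 0, 0.01)
    expect_gte(sse(M, b), fit$fit_residual)
  }
})

test_that("color-map application transforms and clips", {
  img <- array(runif(48), dim = c(4, 4, 3))
  expect_equal(apply_color_map(img, affine_color_map(diag(3)))$data, img)
  hot <- apply_color_map(img, affine_color_map(diag(3) * 3))
  expect_lte(max(hot$data), 1)
  expect_equal(hot$data[img * 3 <= 1], (img * 3)[img * 3 <= 1])
})

test_that("develop recovers an identity-camera scene and names missing charts", {
  sc <- render_scene(n_leaves = 3, seed = 15)
  cfa <- apply_camera_model(sc$image, camera_model(noise_sd = 0))
  out <- develop(cfa, sc$truth$chart$corners, make_reference_chart())
  # demosaicing is only locally exact: compare where the true image is
  # constant over the full 5 x 5 kernel support (chart patch interiors and
  # the surround); color edges and textured regions are its error zone
  range5 <- function(p) {
    lo <- hi <- p
    n1 <- nrow(p); n2 <- ncol(p)
    for (di in -2:2) for (dj in -2:2) {
      sh <- p[pmin(pmax(seq_len(n1) + di, 1), n1),
              pmin(pmax(seq_len(n2) + dj, 1), n2)]
      lo <- pmin(lo, sh); hi <- pmax(hi, sh)
    }
    hi - lo
  }
  flat <- range5(sc$image[, , 1]) == 0 & range5(sc$image[, , 2]) == 0 &
    range5(sc$image[, , 3]) == 0
  expect_gt(sum(flat), 5000)
  err <- apply(abs(out$image$data - sc$image), 3, function(e) max(e[flat]))
  expect_lt(max(err), 1 / 255)
  expect_equal(out$image$colorspace, "corrected")
  expect_true(any(grepl("fit_color_map", out$log)))
  expect_error(develop(cfa, NULL, make_reference_chart()), "chart")
})

test_that("develop undoes a known distortion camera on leaves and chart", {
  sc <- render_scene(n_leaves = 5,
                     leaf_color_spec = list(h = c(0.22, 0.27), s = c(0.5, 0.7),
                                            v = c(0.45, 0.55)),
                     seed = 16)
  cam <- study_camera(noise_sd = 0)
  dev <- develop(apply_camera_model(sc$image, cam), sc$truth$chart$corners,
                 make_reference_chart())
  # the camera applied the distortion's inverse, so the fitted correction
  # must recover the stored forward map itself
  dist <- cam$color_distortion
  expect_equal(dev$map$M, dist$M, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(dev$map$b, dist$b, tolerance = 0.02)
  tm <- sc$truth$true_leaf_mask
  med_true <- apply(sc$image, 3, function(p) median(p[tm]))
  med_dev <- apply(dev$image$data, 3, function(p) median(p[tm]))
  expect_lt(max(abs(med_dev - med_true)), 0.02)
})
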