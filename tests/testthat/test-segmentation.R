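test_that("HSV conversion matches analytic cases and inverts", {
  expect_equal(as.numeric(rgb_to_hsv(c(1, 1, 1))), c(0, 0, 1))
  expect_equal(as.numeric(rgb_to_hsv(c(0, 0.8, 0))), c(1 / 3, 1, 0.8))
  set.seed(41)
  px <- matrix(runif(300), ncol = 3)
  expect_equal(hsv_to_rgb(rgb_to_hsv(px)), px, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(rgb_to_hsv(matrix(2, 1, 3)), "\\[0, 1\\]")
})

test_that("white-background cropping finds the board and its holes", {
  img <- array(1, dim = c(20, 30, 3))
  expect_equal(crop_to_white_background(img)$rect, c(1, 20, 1, 30))

  framed <- array(0.2, dim = c(40, 40, 3))
  framed[10:30, 5:25, ] <- 0.95
  framed[15:20, 10:15, ] <- 0.3      # a dark "leaf" hole inside the board
  cr <- crop_to_white_background(framed)
  expect_equal(cr$rect, c(10, 30, 5, 25))

  sc <- render_scene(n_leaves = 6, seed = 19)
  cr2 <- crop_to_white_background(sc$image)
  tm <- which(sc$truth$true_leaf_mask, arr.ind = TRUE)
  expect_true(all(tm[, 1] >= cr2$rect[1] & tm[, 1] <= cr2$rect[2] &
                    tm[, 2] >= cr2$rect[3] & tm[, 2] <= cr2$rect[4]))

  expect_error(crop_to_white_background(array(0.2, dim = c(10, 10, 3))),
               "manual crop")
})

test_that("the initial HSV gate honours every bound inclusively", {
  params <- mask_params()
  # grid straddling each threshold: (h, s, v, expected)
  cases <- rbind(
    c(0.40, 0.5, 0.5, 1), c(0.401, 0.5, 0.5, 0),
    c(0.875, 0.5, 0.5, 1), c(0.874, 0.5, 0.5, 0),
    c(0.2, 0.2, 0.5, 1), c(0.2, 0.199, 0.5, 0),
    c(0.2, 0.5, 0.9, 1), c(0.2, 0.5, 0.901, 0),
    c(0.2, 1.0, 0.0, 1), c(1.0, 0.5, 0.5, 1))
  hsv <- array(cases[, 1:3], dim = c(nrow(cases), 1, 3))
  got <- initial_mask(hsv, params)
  expect_equal(as.numeric(got), cases[, 4])

  # white background is excluded by saturation, bright saturated green by value
  wb <- array(rep(c(0, 0.02, 0.98), each = 1), dim = c(1, 1, 3))
  expect_false(any(initial_mask(wb, params)))
  green <- array(c(1 / 3, 1, 1), dim = c(1, 1, 3))
  expect_false(any(initial_mask(green, params)))
})

test_that("small-component filtering uses strict fewer-than semantics", {
  mask <- matrix(FALSE, 30, 500)
  mask[2:12, 2:10] <- TRUE           # 11 x 9 = 99 px
  mask[2:11, 400:409] <- TRUE        # 10 x 10 = 100 px
  out <- filter_small_components(mask, 100L, 8L)
  expect_false(any(out[, 1:200]))
  expect_equal(sum(out), 100L)

  empty <- matrix(FALSE, 5, 5)
  expect_identical(filter_small_components(empty, 100L), empty)
})

test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(42)
  for (conn in c(4L, 8L)) {
    mask <- matrix(runif(40 * 40) < 0.35, 40, 40)
    mine <- filter_small_components(mask, 5L, conn)
    lab <- floodfill_labels(mask, conn)
    sizes <- tabulate(lab[lab > 0])
    oracle <- lab > 0 & sizes[pmax(lab, 1)] >= 5
    expect_identical(mine, oracle & mask)
  }
})

test_that("active contours fix sharp two-level masks and heal eroded ones", {
  img <- array(0.95, dim = c(40, 40, 3))
  img[10:30, 10:30, ] <- 0.3
  truth <- matrix(FALSE, 40, 40); truth[10:30, 10:30] <- TRUE
  expect_identical(refine_active_contour(img, truth, 50L), truth)
  expect_identical(refine_active_contour(img, truth, 0L), truth)

  eroded <- matrix(FALSE, 40, 40); eroded[12:28, 12:28] <- TRUE
  healed <- refine_active_contour(img, eroded, 50L)
  iou <- function(a, b) sum(a & b) / sum(a | b)
  expect_gt(iou(healed, truth), iou(eroded, truth))
  expect_equal(iou(healed, truth), 1)

  expect_error(refine_active_contour(img, matrix(FALSE, 40, 40), 50L), "empty")
})

test_that("eroded initialisations improve on rendered leaves too", {
  erode1 <- function(m) m & (ryecolor:::neighbor_count(m) == 4L)
  sc <- render_scene(n_leaves = 5, seed = 23)
  # the contour runs on the cropped board, as in the full chain; otherwise
  # the dark surround competes with the leaves for the inside region
  cr <- crop_to_white_background(sc$image)
  tm <- sc$truth$true_leaf_mask[cr$rect[1]:cr$rect[2], cr$rect[3]:cr$rect[4]]
  shrink <- erode1(erode1(tm))
  healed <- refine_active_contour(cr$image, shrink, 50L)
  iou <- function(a, b) sum(a & b) / sum(a | b)
  expect_gt(iou(healed, tm), iou(shrink, tm))
  expect_gt(iou(healed, tm), 0.95)
})

test_that("saturation re-gating keeps only in-range pixels and is a subset", {
  hsv <- array(runif(60), dim = c(4, 5, 3))
  hsv[1, 1, 2] <- 0.22; hsv[1, 2, 2] <- 0.25
  mask <- matrix(TRUE, 4, 5)
  out <- refine_saturation(mask, hsv, c(0.25, 1))
  expect_false(out[1, 1])
  expect_true(out[1, 2])
  expect_true(all(!out | mask))

  set.seed(44)
  m2 <- matrix(runif(20) < 0.5, 4, 5)
  expect_true(all(refine_saturation(m2, hsv, c(0.25, 1)) <= m2))
})

test_that("full segmentation obeys subset relations and the extraction contract", {
  sc <- render_scene(n_leaves = 6, seed = 25)
  seg <- segment_leaves(sc$image)
  st <- seg$stage_sizes
  expect_lte(st["filtered"], st["initial"])
  expect_lte(st["refined"], st["grown"])
  expect_false(seg$empty)

  # extracted RGB equals the image at the extracted coordinates
  px <- seg$pixels
  expect_equal(px$r, sc$image[cbind(px$row, px$col, 1)])
  expect_equal(px$g, sc$image[cbind(px$row, px$col, 2)])
  expect_equal(px$b, sc$image[cbind(px$row, px$col, 3)])

  # determinism: no randomness anywhere in the masking stage
  expect_identical(seg$mask, segment_leaves(sc$image)$mask)

  s0 <- segment_leaves(render_scene(n_leaves = 0, seed = 25)$image)
  expect_true(s0$empty)
  expect_equal(nrow(s0$pixels), 0L)
})

test_that("segmentation hits high IoU against rendered truth", {
  ious <- vapply(1:8, function(s) {
    sc <- render_scene(n_leaves = 3 + s %% 8, seed = 100 + s)
    seg <- segment_leaves(sc$image)
    tm <- sc$truth$true_leaf_mask
    sum(seg$mask & tm) / sum(seg$mask | tm)
  }, numeric(1))
  expect_gte(median(ious), 0.90)
})
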