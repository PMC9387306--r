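#' Mosaicked sensor frame with camera metadata
#'
#' Container for a color-filter-array image: one measurement per pixel laid
#' out on a Bayer mosaic, plus the metadata the development pipeline needs
#' (black level, white level, white-balance gains, camera-to-RGB matrix).
#'
#' @param data Numeric matrix of sensor counts in \code{[0, white_level]}.
#' @param pattern Bayer layout of the top-left 2 x 2 block.
#' @param black_level,white_level Sensor counts; black < white.
#' @param wb_gains Length-2 \code{c(r, b)} multiplicative gains relative to
#'   green.
#' @param camera_matrix Invertible 3 x 3 camera-space to RGB matrix.
#' @param normalized Internal flag: \code{TRUE} once [linearize()] has run
#'   and \code{data} is float-valued on the 0-1 scale (red/blue sites may
#'   exceed 1 after white balance).
#' @return Object of class \code{cfa_image}.
#' @export
cfa_image <- function(data, pattern, black_level, white_level,
                      wb_gains = c(r = 1, b = 1), camera_matrix = diag(3),
                      normalized = FALSE) {
  pattern <- match.arg(pattern, BAYER_PATTERNS)
  data <- as.matrix(data)
  stopifnot(is.numeric(data), black_level < white_level)
  if (!normalized && (min(data) < 0 || max(data) > white_level)) {
    stop("sensor counts must lie in [0, white_level]")
  }
  camera_matrix <- as.matrix(camera_matrix)
  if (abs(det(camera_matrix)) < 1e-12) stop("camera_matrix must be invertible")
  structure(list(data = data, pattern = pattern,
                 black_level = black_level, white_level = white_level,
                 wb_gains = c(r = unname(wb_gains[1]), b = unname(wb_gains[2])),
                 camera_matrix = camera_matrix, normalized = normalized),
            class = "cfa_image")
}

#' @export
print.cfa_image <- function(x, ...) {
  cat(sprintf("CFA image %d x %d, pattern %s, black %s, white %s%s\n",
              nrow(x$data), ncol(x$data), x$pattern,
              format(x$black_level), format(x$white_level),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' RGB image container
#'
#' An H x W x 3 array with a colorspace tag recording how far through the
#' development pipeline it has travelled: \code{"camera"} (demosaiced, still
#' in camera color space), \code{"rgb"} (after the camera matrix) or
#' \code{"corrected"} (after the chart-fitted affine map, clipped to
#' \code{[0, 1]}).
#'
#' @param data H x W x 3 numeric array.
#' @param colorspace One of \code{"camera"}, \code{"rgb"}, \code{"corrected"}.
#' @export
rgb_image <- function(data, colorspace = c("corrected", "rgb", "camera")) {
  colorspace <- match.arg(colorspace)
  stopifnot(is.numeric(data), length(dim(data)) == 3L, dim(data)[3] == 3L)
  if (colorspace == "corrected" && (min(data) < -1e-9 || max(data) > 1 + 1e-9)) {
    stop("corrected images must be clipped to [0, 1]")
  }
  structure(list(data = data, colorspace = colorspace), class = "rgb_image")
}

# Accept either a bare array or an rgb_image and return the array.
image_data <- function(img) {
  if (inherits(img, "rgb_image")) img$data else img
}

#' Linearize a CFA frame
#'
#' The first development stages: subtract the black level, floor negative
#' values at zero, normalize by the white-minus-black range, and white
#' balance by scaling red and blue photosites relative to green. Green
#' sites are untouched; red/blue sites may exceed 1 after their gains.
#'
#' @param cfa A [cfa_image()] in raw counts.
#' @return A [cfa_image()] with \code{normalized = TRUE}.
#' @export
linearize <- function(cfa) {
  stopifnot(inherits(cfa, "cfa_image"))
  if (cfa$normalized) stop("CFA is already normalized")
  x <- pmax(cfa$data - cfa$black_level, 0) / (cfa$white_level - cfa$black_level)
  sites <- bayer_sites(cfa$pattern, nrow(x), ncol(x))
  x[sites == "R"] <- x[sites == "R"] * cfa$wb_gains["r"]
  x[sites == "B"] <- x[sites == "B"] * cfa$wb_gains["b"]
  out <- cfa
  out$data <- x
  out$normalized <- TRUE
  out
}

# Round a normalized image to the 16-bit integer grid (values above 1 keep
# their scale; only the grid spacing is imposed).
quantize_u16 <- function(x) round(x * 65535) / 65535

# --- demosaicing: gradient-corrected linear interpolation ----------------

# The four 5 x 5 interpolation kernels (each divided by 8):
#   cross: estimate G at an R or B site
#   row:   estimate the same-row chroma at a G site
#   col:   estimate the same-column chroma at a G site (transpose of row)
#   diag:  estimate the opposite chroma at an R or B site
mhc_kernels <- function() {
  cross <- matrix(c(
     0,  0, -1,  0,  0,
     0,  0,  2,  0,  0,
    -1,  2,  4,  2, -1,
     0,  0,  2,  0,  0,
     0,  0, -1,  0,  0), 5, 5, byrow = TRUE) / 8
  row <- matrix(c(
     0,  0, 0.5, 0,  0,
     0, -1,  0, -1,  0,
    -1,  4,  5,  4, -1,
     0, -1,  0, -1,  0,
     0,  0, 0.5, 0,  0), 5, 5, byrow = TRUE) / 8
  diagk <- matrix(c(
       0,  0, -1.5,  0,    0,
       0,  2,  0,    2,    0,
    -1.5,  0,  6,    0, -1.5,
       0,  2,  0,    2,    0,
       0,  0, -1.5,  0,    0), 5, 5, byrow = TRUE) / 8
  list(cross = cross, row = row, col = t(row), diag = diagk)
}

# Reflective (symmetric) padding by `k` pixels on each side.
pad_reflect <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  if (nr < k || nc < k) stop("image too small to pad")
  ri <- c(k:1, seq_len(nr), nr:(nr - k + 1))
  ci <- c(k:1, seq_len(nc), nc:(nc - k + 1))
  x[ri, ci]
}

# 2-D convolution (correlation; all kernels here are symmetric) of the
# reflectively padded image, returning the valid central part. Implemented
# as a sum of shifted copies, which is fast in R.
conv5 <- function(x, kern) {
  k <- (nrow(kern) - 1L) / 2L
  xp <- pad_reflect(x, k)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (di in -k:k) for (dj in -k:k) {
    w <- kern[di + k + 1L, dj + k + 1L]
    if (w != 0) {
      out <- out + w * xp[(1L + k + di):(nr + k + di),
                          (1L + k + dj):(nc + k + dj)]
    }
  }
  out
}

#' Demosaic by gradient-corrected linear interpolation
#'
#' Reconstructs the two missing channels at every photosite using bilinear
#' interpolation plus a scaled Laplacian correction from the measured
#' channel (the standard 5 x 5 kernel set). Borders are handled by
#' reflective padding. The output is in the camera's color space.
#'
#' @param cfa A normalized [cfa_image()] (run [linearize()] first), or a
#'   plain numeric matrix plus \code{pattern}.
#' @param pattern Bayer pattern; taken from \code{cfa} when it is a
#'   \code{cfa_image}.
#' @return An [rgb_image()] tagged \code{"camera"}.
#' @export
demosaic_mhc <- function(cfa, pattern = NULL) {
  if (inherits(cfa, "cfa_image")) {
    if (!cfa$normalized) stop("linearize the CFA before demosaicing")
    pattern <- cfa$pattern
    x <- cfa$data
  } else {
    x <- as.matrix(cfa)
    pattern <- match.arg(pattern, BAYER_PATTERNS)
  }
  nr <- nrow(x); nc <- ncol(x)
  if (nr < 5L || nc < 5L) stop("image must be at least 5 x 5 to demosaic")

  kerns <- mhc_kernels()
  g_cross <- conv5(x, kerns$cross)
  c_row   <- conv5(x, kerns$row)
  c_col   <- conv5(x, kerns$col)
  c_diag  <- conv5(x, kerns$diag)

  sites <- bayer_sites(pattern, nr, nc)
  at_R <- sites == "R"; at_G <- sites == "G"; at_B <- sites == "B"
  # G sites split by whether red neighbours sit in the same row
  red_cols <- apply(sites == "R", 2, any)
  g_in_r_row <- at_G & matrix(apply(at_R, 1, any), nr, nc) &
    !matrix(red_cols, nr, nc, byrow = TRUE)

  R <- G <- B <- x
  G[at_R | at_B] <- g_cross[at_R | at_B]
  R[at_G &  g_in_r_row] <- c_row[at_G &  g_in_r_row]
  R[at_G & !g_in_r_row] <- c_col[at_G & !g_in_r_row]
  B[at_G & !g_in_r_row] <- c_row[at_G & !g_in_r_row]
  B[at_G &  g_in_r_row] <- c_col[at_G &  g_in_r_row]
  R[at_B] <- c_diag[at_B]
  B[at_R] <- c_diag[at_R]

  rgb_image(array(c(R, G, B), dim = c(nr, nc, 3L)), colorspace = "camera")
}

#' Camera color space to RGB
#'
#' Per-pixel multiplication by the camera metadata's 3 x 3 matrix. No
#' clipping is applied at this stage.
#'
#' @param img [rgb_image()] in camera space (or a bare array).
#' @param matrix Invertible 3 x 3 matrix.
#' @export
camera_to_rgb <- function(img, matrix) {
  matrix <- as.matrix(matrix)
  if (abs(det(matrix)) < 1e-12) stop("camera matrix is singular")
  rgb_image(transform_colors(image_data(img), matrix), colorspace = "rgb")
}

#' Measure the 24 chart patches in an image
#'
#' Maps the 4 x 6 patch grid from the chart's four outer corners into the
#' image by bilinear (projective for a rendered rectangle) interpolation
#' and measures each patch as the per-channel median over the central 50%
#' of its area. Patch order is row-major from the first corner.
#'
#' @param img [rgb_image()] or H x W x 3 array.
#' @param chart_corners 4 x 2 matrix of (row, col) coordinates in the order
#'   top-left, top-right, bottom-right, bottom-left of the patch grid.
#' @param grid_shape Patch grid, default \code{c(4, 6)}.
#' @return 24 x 3 matrix of measured patch colors.
#' @export
measure_chart <- function(img, chart_corners, grid_shape = c(4L, 6L)) {
  x <- image_data(img)
  corners <- as.matrix(chart_corners)
  stopifnot(all(dim(corners) == c(4L, 2L)))
  nr <- dim(x)[1]; nc <- dim(x)[2]
  if (any(corners[, 1] < 1) || any(corners[, 1] > nr) ||
      any(corners[, 2] < 1) || any(corners[, 2] > nc)) {
    stop("chart corners fall outside the image")
  }
  # reject (near-)collinear corner sets: they cannot span a patch grid
  a <- corners[2, ] - corners[1, ]; b <- corners[4, ] - corners[1, ]
  if (abs(a[1] * b[2] - a[2] * b[1]) < 4) {
    stop("chart corners are collinear or degenerate")
  }

  gr <- grid_shape[1]; gc <- grid_shape[2]
  # bilinear map from unit square (u across columns, v down rows) to image
  bil <- function(u, v) {
    (1 - v) * ((1 - u) * corners[1, ] + u * corners[2, ]) +
      v       * ((1 - u) * corners[4, ] + u * corners[3, ])
  }
  measured <- matrix(NA_real_, gr * gc, 3L)
  half <- 0.25 * sqrt(0.5)  # half-extent of a central-50%-area window
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    us <- (j - 1 + c(0.5 - half, 0.5 + half)) / gc
    vs <- (i - 1 + c(0.5 - half, 0.5 + half)) / gr
    ptl <- bil(us[1], vs[1]); pbr <- bil(us[2], vs[2])
    rows <- max(1L, ceiling(min(ptl[1], pbr[1]))):min(nr, floor(max(ptl[1], pbr[1])))
    cols <- max(1L, ceiling(min(ptl[2], pbr[2]))):min(nc, floor(max(ptl[2], pbr[2])))
    patch <- x[rows, cols, , drop = FALSE]
    measured[(i - 1) * gc + j, ] <- apply(patch, 3, stats::median)
  }
  colnames(measured) <- c("r", "g", "b")
  measured
}

#' Fit the affine color correction from chart patches
#'
#' Ordinary least squares, one regression per output channel, of the
#' reference patch colors on the measured colors plus an intercept. This is
#' the affine transform minimizing the sum of squared deviations between
#' corrected and reference colors over the 24 patches.
#'
#' @param measured 24 x 3 matrix of patch colors measured in the image.
#' @param reference 24 x 3 matrix of known patch colors, or a
#'   [make_reference_chart()] object.
#' @return An [affine_color_map()] with \code{fit_residual} filled in.
#' @export
fit_affine_color_map <- function(measured, reference) {
  if (inherits(reference, "chart_reference")) reference <- reference$patch_colors
  measured <- as.matrix(measured); reference <- as.matrix(reference)
  stopifnot(nrow(measured) == nrow(reference), ncol(measured) == 3L,
            ncol(reference) == 3L)
  X <- cbind(measured, 1)
  if (qr(X)$rank < 4L) {
    stop("measured patch colors are rank-deficient; ",
         "cannot identify an affine color map")
  }
  beta <- qr.solve(X, reference)        # 4 x 3: rows = (r, g, b, intercept)
  M <- t(beta[1:3, , drop = FALSE])
  b <- as.numeric(beta[4, ])
  resid <- reference - X %*% beta
  affine_color_map(M, b, fit_residual = sum(resid^2))
}

#' Apply a fitted color map to an image
#'
#' Per-pixel \eqn{M c + b}, clipped to \code{[0, 1]} so downstream HSV
#' conversion sees bounded values.
#'
#' @param img [rgb_image()] or array.
#' @param map [affine_color_map()].
#' @return [rgb_image()] tagged \code{"corrected"}.
#' @export
apply_color_map <- function(img, map) {
  stopifnot(inherits(map, "affine_color_map"))
  out <- transform_colors(image_data(img), map$M, map$b)
  rgb_image(clip01(out), colorspace = "corrected")
}

#' Develop a CFA frame into a color-corrected RGB image
#'
#' Runs the full development chain: linearize (black subtraction,
#' normalization, white balance), optional 16-bit quantization, demosaic by
#' gradient-corrected linear interpolation, camera-to-RGB matrix, chart
#' patch measurement, affine color-map fit, and color-map application with
#' final clipping to \code{[0, 1]}.
#'
#' @param cfa A raw [cfa_image()].
#' @param chart_corners 4 x 2 matrix locating the chart's patch grid (see
#'   [measure_chart()]).
#' @param reference [make_reference_chart()] object (or 24 x 3 matrix).
#' @param quantize Quantize to the unsigned 16-bit grid between
#'   linearization and demosaicing (default \code{TRUE}).
#' @return List with \code{image} (corrected [rgb_image()]), \code{map}
#'   (the fitted [affine_color_map()]) and \code{log} (per-stage summary
#'   strings).
#' @export
develop <- function(cfa, chart_corners, reference, quantize = TRUE) {
  stopifnot(inherits(cfa, "cfa_image"))
  if (is.null(chart_corners)) {
    stop("chart patch identification failed: chart_corners are missing")
  }
  log <- character()
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- paste0(stage, ": ", msg)
  }

  lin <- linearize(cfa)
  note("linearize", sprintf("range %.4f-%.4f", min(lin$data), max(lin$data)))
  if (quantize) {
    lin$data <- quantize_u16(lin$data)
    note("quantize", "snapped to unsigned 16-bit grid")
  }
  cam_img <- demosaic_mhc(lin)
  note("demosaic", "gradient-corrected linear interpolation, 5x5 kernels")
  rgb <- camera_to_rgb(cam_img, cfa$camera_matrix)
  note("camera_to_rgb", "applied camera matrix")
  measured <- measure_chart(rgb, chart_corners)
  note("measure_chart", sprintf("24 patches, mean level %.3f", mean(measured)))
  map <- fit_affine_color_map(measured, reference)
  note("fit_color_map", sprintf("SSE over patches %.3g", map$fit_residual))
  corrected <- apply_color_map(rgb, map)
  note("apply_color_map", "corrected and clipped to [0, 1]")

  list(image = corrected, map = map, log = log)
}
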