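#' Affine color map
#'
#' A color transform of the form \eqn{c \mapsto M c + b} with a 3 x 3
#' matrix \code{M} and offset \code{b}. Used both as the fitted correction
#' (estimated from chart patches) and as the known forward distortion of
#' the synthetic camera.
#'
#' @param M 3 x 3 numeric matrix.
#' @param b Numeric offset of length 3 (default zero).
#' @param fit_residual Sum of squared deviations over the fitting patches,
#'   if the map was estimated; \code{NA} for a constructed map.
#' @return Object of class \code{affine_color_map}.
#' @export
affine_color_map <- function(M, b = c(0, 0, 0), fit_residual = NA_real_) {
  M <- as.matrix(M)
  stopifnot(is.numeric(M), all(dim(M) == c(3L, 3L)),
            is.numeric(b), length(b) == 3L)
  if (!is.na(fit_residual) && fit_residual < 0) {
    stop("fit_residual must be non-negative")
  }
  structure(list(M = M, b = as.numeric(b), fit_residual = fit_residual),
            class = "affine_color_map")
}

#' @export
print.affine_color_map <- function(x, ...) {
  cat("Affine color map c -> M c + b\n")
  print(round(x$M, 4))
  cat("offset b:", paste(round(x$b, 4), collapse = ", "), "\n")
  if (!is.na(x$fit_residual)) {
    cat("fit residual (SSE over patches):", signif(x$fit_residual, 4), "\n")
  }
  invisible(x)
}

invert_color_map <- function(map) {
  Minv <- tryCatch(solve(map$M),
                   error = function(e) stop("color map matrix is singular"))
  affine_color_map(Minv, as.numeric(-Minv %*% map$b))
}

BAYER_PATTERNS <- c("RGGB", "BGGR", "GRBG", "GBRG")

#' Synthetic camera model
#'
#' Forward model of the sensor chain that the development pipeline inverts:
#' a known color distortion, a camera-to-RGB color matrix, white-balance
#' gains on red and blue photosites, Bayer mosaicing, scaling to sensor
#' counts between a black and a white level, additive Gaussian read noise,
#' and integer quantization.
#'
#' @param bayer_pattern One of \code{"RGGB"}, \code{"BGGR"}, \code{"GRBG"},
#'   \code{"GBRG"} (layout of the top-left 2 x 2 sensor block).
#' @param black_level,white_level Sensor counts; \code{black_level <
#'   white_level}. Default 0 and 65535 (16-bit sensor).
#' @param wb_gains Length-2 numeric \code{c(r, b)}: the gains the developer
#'   will multiply red/blue sites by, relative to green.
#' @param camera_matrix Invertible 3 x 3 camera-space to RGB matrix.
#' @param color_distortion [affine_color_map()] applied (inverted) in the
#'   forward direction, emulating the residual error that chart calibration
#'   must undo.
#' @param noise_sd Additive Gaussian noise sd in normalized (0-1) sensor
#'   units; 0 disables noise.
#' @param seed Integer seed for the noise draw.
#' @return Object of class \code{camera_model}.
#' @export
camera_model <- function(bayer_pattern = "RGGB",
                         black_level = 0L,
                         white_level = 65535L,
                         wb_gains = c(r = 1, b = 1),
                         camera_matrix = diag(3),
                         color_distortion = affine_color_map(diag(3)),
                         noise_sd = 0,
                         seed = 1L) {
  bayer_pattern <- match.arg(bayer_pattern, BAYER_PATTERNS)
  stopifnot(black_level < white_level, noise_sd >= 0,
            length(wb_gains) == 2L, all(wb_gains > 0))
  camera_matrix <- as.matrix(camera_matrix)
  if (abs(det(camera_matrix)) < 1e-12) stop("camera_matrix must be invertible")
  if (abs(det(color_distortion$M)) < 1e-12) {
    stop("color_distortion matrix must be invertible")
  }
  structure(list(bayer_pattern = bayer_pattern,
                 black_level = black_level, white_level = white_level,
                 wb_gains = c(r = unname(wb_gains[1]), b = unname(wb_gains[2])),
                 camera_matrix = camera_matrix,
                 color_distortion = color_distortion,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "camera_model")
}

# Matrix of channel labels ("R", "G", "B") for an nr x nc sensor under a
# Bayer pattern. Pattern letters are row-major over the top-left 2 x 2.
bayer_sites <- function(pattern, nr, nc) {
  letters4 <- strsplit(pattern, "")[[1]]
  block <- matrix(letters4, 2, 2, byrow = TRUE)
  block[((seq_len(nr) - 1L) %% 2L) + 1L, ((seq_len(nc) - 1L) %% 2L) + 1L]
}

#' Apply the forward camera model to a scene
#'
#' Converts a ground-truth RGB image into the mosaicked sensor frame a raw
#' file would hold. This is the exact inverse composition of the
#' development pipeline's linearization, white balance, color-space and
#' chart-correction stages, so with zero noise [develop()] recovers the
#' scene up to demosaicing and quantization error.
#'
#' @param img H x W x 3 RGB array in \code{[0, 1]}; H and W must be even.
#' @param cam A [camera_model()].
#' @return Object of class \code{cfa_image}: list with integer matrix
#'   \code{data} plus the metadata fields of the camera model needed for
#'   development.
#' @export
apply_camera_model <- function(img, cam) {
  stopifnot(inherits(cam, "camera_model"), length(dim(img)) == 3L)
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9) stop("img must lie in [0, 1]")
  nr <- dim(img)[1]; nc <- dim(img)[2]
  if (nr %% 2L || nc %% 2L) stop("image dimensions must be even for mosaicing")

  inv_dist <- invert_color_map(cam$color_distortion)
  x <- transform_colors(img, inv_dist$M, inv_dist$b)
  x <- transform_colors(x, solve(cam$camera_matrix))
  # undo the white balance the developer will apply
  x[, , 1] <- x[, , 1] / cam$wb_gains["r"]
  x[, , 3] <- x[, , 3] / cam$wb_gains["b"]

  sites <- bayer_sites(cam$bayer_pattern, nr, nc)
  chan <- match(sites, c("R", "G", "B"))
  idx <- cbind(as.vector(row(sites)), as.vector(col(sites)), as.vector(chan))
  cfa <- matrix(x[idx], nr, nc)

  counts <- cam$black_level + cfa * (cam$white_level - cam$black_level)
  if (cam$noise_sd > 0) {
    counts <- counts + local_rng(cam$seed, stats::rnorm(
      length(counts), 0, cam$noise_sd * (cam$white_level - cam$black_level)))
  }
  counts <- round(pmin(pmax(counts, 0), cam$white_level))

  cfa_image(counts, pattern = cam$bayer_pattern,
            black_level = cam$black_level, white_level = cam$white_level,
            wb_gains = cam$wb_gains, camera_matrix = cam$camera_matrix)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards; generators stay pure in (params, seed).
local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
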