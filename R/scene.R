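#' Render a synthetic leaf-on-white scene
#'
#' Draws the ground-truth scene the camera model photographs: a dark
#' surround, a white board carrying elongated leaf blades, and the 24-patch
#' reference chart in a strip above the board. The board is near-white with
#' slight texture (channel values 0.92-1.0) so that the segmentation
#' saturation gate is exercised rather than vacuous. Blades are parametric:
#' random position, orientation, length, width taper and curvature, each
#' filled with a single color drawn from \code{leaf_color_spec}.
#'
#' @param n_leaves Number of blades (>= 0).
#' @param leaf_color_spec List with elements \code{h}, \code{s}, \code{v},
#'   each a length-2 range on \code{[0, 1]}; one HSV color is drawn
#'   uniformly per leaf. Default is a green-brown foliage range.
#' @param size Image dimensions \code{c(rows, cols)}; both must be even
#'   (the camera mosaics in 2 x 2 blocks).
#' @param chart A [make_reference_chart()] object.
#' @param seed Integer seed; the renderer is a pure function of its
#'   arguments and the seed.
#' @return List with \code{image} (H x W x 3 array in \code{[0, 1]}) and
#'   \code{truth}, a \code{scene_truth} list: \code{true_image},
#'   \code{true_leaf_mask}, \code{leaf_colors} (n_leaves x 3),
#'   \code{chart} (with \code{corners} filled in) and \code{board_rect}
#'   (\code{c(r0, r1, c0, c1)}).
#' @export
render_scene <- function(n_leaves = 5L,
                         leaf_color_spec = list(h = c(0.10, 0.36),
                                                s = c(0.40, 0.85),
                                                v = c(0.30, 0.75)),
                         size = c(200L, 288L),
                         chart = make_reference_chart(),
                         seed = 1L) {
  stopifnot(inherits(chart, "chart_reference"), n_leaves >= 0)
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  if (nr %% 2L || nc %% 2L) stop("scene dimensions must be even")

  # layout: chart strip on top, white board below
  patch_px <- min((nr %/% 3 - 6) %/% 4, (nc - 16) %/% 6)
  if (patch_px < 6L) stop("scene too small to contain the reference chart")
  chart_r0 <- 4L
  chart_c0 <- (nc - 6L * patch_px) %/% 2L + 1L
  board_r0 <- chart_r0 + 4L * patch_px + 6L
  board <- c(board_r0, nr - 2L, 4L, nc - 3L)
  if (board[2] - board[1] < 40L || board[4] - board[3] < 40L) {
    stop("scene too small to hold leaves below the chart")
  }

  local_rng(seed, {
    img <- array(0.35, dim = c(nr, nc, 3L))   # achromatic dark surround

    # white board with slight per-pixel texture
    brows <- board[1]:board[2]; bcols <- board[3]:board[4]
    nb <- length(brows) * length(bcols)
    for (ch in 1:3) {
      img[brows, bcols, ch] <- 0.92 + 0.08 * stats::runif(nb)
    }

    # chart patches, row-major over the 4 x 6 grid
    for (i in 1:4) for (j in 1:6) {
      rows <- (chart_r0 + (i - 1L) * patch_px):(chart_r0 + i * patch_px - 1L)
      cols <- (chart_c0 + (j - 1L) * patch_px):(chart_c0 + j * patch_px - 1L)
      col3 <- chart$patch_colors[(i - 1L) * 6L + j, ]
      for (ch in 1:3) img[rows, cols, ch] <- col3[ch]
    }
    chart$corners <- rbind(
      c(chart_r0 - 0.5, chart_c0 - 0.5),
      c(chart_r0 - 0.5, chart_c0 + 6 * patch_px - 0.5),
      c(chart_r0 + 4 * patch_px - 0.5, chart_c0 + 6 * patch_px - 0.5),
      c(chart_r0 + 4 * patch_px - 0.5, chart_c0 - 0.5))
    dimnames(chart$corners) <- list(c("tl", "tr", "br", "bl"), c("row", "col"))

    mask <- matrix(FALSE, nr, nc)
    leaf_colors <- matrix(numeric(0), 0, 3)
    if (n_leaves > 0) {
      leaf_hsv <- cbind(
        stats::runif(n_leaves, leaf_color_spec$h[1], leaf_color_spec$h[2]),
        stats::runif(n_leaves, leaf_color_spec$s[1], leaf_color_spec$s[2]),
        stats::runif(n_leaves, leaf_color_spec$v[1], leaf_color_spec$v[2]))
      leaf_colors <- hsv_to_rgb(leaf_hsv)
      # harvested material lies in a loose pile, so blades cluster around a
      # common centre and overlap, as in the photographed scenes
      inner <- board + c(4L, -4L, 4L, -4L)
      pad <- 36
      pile <- c(stats::runif(1, inner[1] + pad, inner[2] - pad),
                stats::runif(1, inner[3] + pad, inner[4] - pad))
      for (k in seq_len(n_leaves)) {
        blade <- rasterize_blade(inner, pile)
        mask[blade] <- TRUE
        # within-leaf shading: multiplicative brightness jitter preserves
        # hue and saturation while giving each leaf a continuous texture
        shade <- stats::runif(nrow(blade), 0.93, 1.07)
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[blade] <- pmin(leaf_colors[k, ch] * shade, 1)
          img[, , ch] <- plane
        }
      }
    }

    truth <- structure(list(true_image = img, true_leaf_mask = mask,
                            leaf_colors = leaf_colors, chart = chart,
                            board_rect = board),
                       class = "scene_truth")
    list(image = img, truth = truth)
  })
}

# Draw one tapered, slightly curved blade inside the rectangle
# `inner` = c(r0, r1, c0, c1); returns a logical matrix-index of its pixels
# (linear indices into an nr x nc matrix are avoided: returns a 2-col
# coordinate matrix usable as mask[blade] <- TRUE).
rasterize_blade <- function(inner, pile = NULL) {
  half_len <- stats::runif(1, 18, 28)
  half_wid <- stats::runif(1, 5, 9)
  theta <- stats::runif(1, 0, pi)
  curv <- stats::runif(1, -0.25, 0.25)
  pad <- half_len + half_wid + 2
  if (is.null(pile)) {
    cy <- stats::runif(1, inner[1] + pad, inner[2] - pad)
    cx <- stats::runif(1, inner[3] + pad, inner[4] - pad)
  } else {
    cy <- pile[1] + stats::rnorm(1, 0, 7)
    cx <- pile[2] + stats::rnorm(1, 0, 7)
    cy <- min(max(cy, inner[1] + pad), inner[2] - pad)
    cx <- min(max(cx, inner[3] + pad), inner[4] - pad)
  }
  # if the inner area is tight, fall back to its centre
  if (is.na(cy) || cy < inner[1] + pad) cy <- (inner[1] + inner[2]) / 2
  if (is.na(cx) || cx < inner[3] + pad) cx <- (inner[3] + inner[4]) / 2

  t <- seq(-1, 1, length.out = 160)
  dir <- c(sin(theta), cos(theta))
  nrm <- c(-dir[2], dir[1])
  py <- cy + t * half_len * dir[1] + curv * t^2 * half_len * nrm[1]
  px <- cx + t * half_len * dir[2] + curv * t^2 * half_len * nrm[2]
  rad <- pmax(half_wid * sqrt(pmax(1 - t^2, 0)), 0.6)

  r0 <- max(inner[1], floor(min(py - rad))); r1 <- min(inner[2], ceiling(max(py + rad)))
  c0 <- max(inner[3], floor(min(px - rad))); c1 <- min(inner[4], ceiling(max(px + rad)))
  rows <- r0:r1; cols <- c0:c1
  gy <- matrix(rows, length(rows), length(cols))
  gx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  inside <- matrix(FALSE, length(rows), length(cols))
  for (k in seq_along(t)) {
    inside <- inside | ((gy - py[k])^2 + (gx - px[k])^2 <= rad[k]^2)
  }
  cbind(as.vector(gy)[as.vector(inside)], as.vector(gx)[as.vector(inside)])
}
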