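#' Reference color chart
#'
#' Builds the 24-patch reference chart used for affine color calibration.
#' The default patch set is a canonical 4 x 6 ColorChecker-style palette in
#' sRGB, scaled to \code{[0, 1]}. Any user-supplied 24 x 3 color matrix can
#' be used instead, provided it is not degenerate for affine fitting: the
#' 24 x 3 matrix augmented with a constant column must have rank 4,
#' otherwise the least-squares color map is unidentifiable.
#'
#' @param colors Optional 24 x 3 numeric matrix of patch colors in
#'   \code{[0, 1]}, row-major over the 4 x 6 grid (top-left patch first).
#' @return An object of class \code{chart_reference}: a list with
#'   \code{patch_colors} (24 x 3 matrix), \code{grid_shape} (\code{c(4, 6)})
#'   and \code{corners} (\code{NULL} until the chart is placed in a scene;
#'   then a 4 x 2 matrix of (row, col) image coordinates in the order
#'   top-left, top-right, bottom-right, bottom-left).
#' @export
make_reference_chart <- function(colors = NULL) {
  if (is.null(colors)) {
    colors <- default_chart_colors()
  }
  colors <- as.matrix(colors)
  if (!is.numeric(colors) || nrow(colors) != 24L || ncol(colors) != 3L) {
    stop("chart colors must be a 24 x 3 numeric matrix")
  }
  if (anyNA(colors) || any(colors < 0) || any(colors > 1)) {
    stop("chart colors must lie in [0, 1] with no missing values")
  }
  if (qr(cbind(colors, 1))$rank < 4L) {
    stop("chart colors are rank-deficient: the 24 patches (plus intercept) ",
         "must span rank 4 or the affine color map cannot be identified")
  }
  structure(
    list(patch_colors = colors, grid_shape = c(4L, 6L), corners = NULL),
    class = "chart_reference"
  )
}

# Canonical 24-patch palette (sRGB 8-bit averages of the classic chart),
# row-major over the 4 x 6 grid.
default_chart_colors <- function() {
  rgb8 <- matrix(c(
    115,  82,  68,   194, 150, 130,    98, 122, 157,    87, 108,  67,
    133, 128, 177,   103, 189, 170,   214, 126,  44,    80,  91, 166,
    193,  90,  99,    94,  60, 108,   157, 188,  64,   224, 163,  46,
     56,  61, 150,    70, 148,  73,   175,  54,  60,   231, 199,  31,
    187,  86, 149,     8, 133, 161,   243, 243, 242,   200, 200, 200,
    160, 160, 160,   122, 122, 121,    85,  85,  85,    52,  52,  52
  ), ncol = 3, byrow = TRUE)
  colnames(rgb8) <- c("r", "g", "b")
  rgb8 / 255
}

#' @export
print.chart_reference <- function(x, ...) {
  cat("Reference chart:", nrow(x$patch_colors), "patches,",
      x$grid_shape[1], "x", x$grid_shape[2], "grid\n")
  if (!is.null(x$corners)) {
    cat("Placed at corners (row, col):\n")
    print(round(x$corners, 1))
  }
  invisible(x)
}
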