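#' RGB to HSV conversion for image arrays
#'
#' Standard hexcone conversion. Hue, saturation and value are all on
#' \code{[0, 1]}; hue wraps at 1 (red). Achromatic pixels (max = min) get
#' hue 0 and saturation 0.
#'
#' @param img Either an H x W x 3 array or an n x 3 matrix of RGB values in
#'   \code{[0, 1]}.
#' @return Same shape as the input, channels reinterpreted as H, S, V.
#' @export
rgb_to_hsv <- function(img) {
  stopifnot(is.numeric(img))
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    stop("RGB values must lie in [0, 1]")
  }
  flat <- flatten_channels(img)
  hsv <- t(grDevices::rgb2hsv(t(flat), maxColorValue = 1))
  colnames(hsv) <- c("h", "s", "v")
  unflatten_channels(hsv, img)
}

#' HSV to RGB conversion
#'
#' Exact inverse of [rgb_to_hsv()] (up to floating point), vectorised over
#' pixels. Used by the scene renderer to draw colors specified in HSV.
#'
#' @param hsv H x W x 3 array or n x 3 matrix, channels H, S, V in [0, 1].
#' @return Same shape, channels R, G, B in [0, 1].
#' @export
hsv_to_rgb <- function(hsv) {
  flat <- flatten_channels(hsv)
  h <- flat[, 1] %% 1
  s <- flat[, 2]
  v <- flat[, 3]
  i <- floor(h * 6)
  f <- h * 6 - i
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  i <- i %% 6
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- cbind(r = r, g = g, b = b)
  unflatten_channels(out, hsv)
}

# Coerce an H x W x 3 array or n x 3 matrix to an n x 3 matrix.
flatten_channels <- function(x) {
  if (length(dim(x)) == 3L) {
    stopifnot(dim(x)[3] == 3L)
    matrix(x, ncol = 3L)
  } else if (is.matrix(x) && ncol(x) == 3L) {
    x
  } else if (is.numeric(x) && length(x) == 3L) {
    matrix(x, ncol = 3L)
  } else {
    stop("expected an H x W x 3 array or an n x 3 matrix")
  }
}

# Reshape an n x 3 matrix back to the shape of the template input.
unflatten_channels <- function(flat, template) {
  if (length(dim(template)) == 3L) {
    array(flat, dim = dim(template))
  } else if (is.matrix(template)) {
    flat
  } else {
    drop(flat)
  }
}

# Per-pixel affine transform of an image or pixel matrix: c -> M c + b.
transform_colors <- function(img, M, b = c(0, 0, 0)) {
  flat <- flatten_channels(img)
  out <- flat %*% t(M)
  out <- sweep(out, 2, b, "+")
  unflatten_channels(out, img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
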