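#' Segmentation parameters
#'
#' Thresholds and iteration counts for the leaf-masking stage. Defaults are
#' the pipeline's standard values: hue kept on the union of
#' \code{[0, 0.4]} (yellow-green) and \code{[0.875, 1]} (red wraparound),
#' saturation \code{[0.2, 1]} and value \code{[0, 0.9]} for the initial
#' gate; connected components under 100 pixels removed; 50 sweeps of
#' region-based active contours; a final saturation re-gate at
#' \code{[0.25, 1]}. All interval bounds are inclusive.
#'
#' @param hue_ranges 2 x 2 matrix, one row per kept hue interval.
#' @param sat_range,val_range,refine_sat_range Length-2 closed intervals.
#' @param min_component_px Components with fewer pixels are removed.
#' @param ac_iterations Active-contour sweeps (0 disables refinement).
#' @param connectivity 4 or 8 (component labelling neighbourhood).
#' @return Object of class \code{mask_params}.
#' @export
mask_params <- function(hue_ranges = rbind(c(0, 0.4), c(0.875, 1)),
                        sat_range = c(0.2, 1),
                        val_range = c(0, 0.9),
                        min_component_px = 100L,
                        ac_iterations = 50L,
                        refine_sat_range = c(0.25, 1),
                        connectivity = 8L) {
  hue_ranges <- as.matrix(hue_ranges)
  stopifnot(ncol(hue_ranges) == 2L, all(hue_ranges >= 0), all(hue_ranges <= 1),
            all(sat_range >= 0), all(sat_range <= 1),
            all(val_range >= 0), all(val_range <= 1),
            all(refine_sat_range >= 0), all(refine_sat_range <= 1),
            min_component_px >= 1L, ac_iterations >= 0L,
            connectivity %in% c(4L, 8L))
  structure(list(hue_ranges = hue_ranges, sat_range = sat_range,
                 val_range = val_range,
                 min_component_px = as.integer(min_component_px),
                 ac_iterations = as.integer(ac_iterations),
                 refine_sat_range = refine_sat_range,
                 connectivity = as.integer(connectivity)),
            class = "mask_params")
}

#' Crop an image to its white background board
#'
#' Finds the largest connected near-white region (all channels at or above
#' \code{white_thresh}) and returns its bounding box, which automatically
#' includes the darker leaves lying on the board as interior holes. A
#' manual rectangle can override detection.
#'
#' @param img [rgb_image()] or H x W x 3 array.
#' @param white_thresh Channel threshold defining "near white".
#' @param min_frac Minimum fraction of near-white pixels required.
#' @param rect Optional manual crop \code{c(r0, r1, c0, c1)}.
#' @return List with \code{image} (cropped array) and \code{rect}.
#' @export
crop_to_white_background <- function(img, white_thresh = 0.85,
                                     min_frac = 0.05, rect = NULL) {
  x <- image_data(img)
  if (is.null(rect)) {
    white <- x[, , 1] >= white_thresh & x[, , 2] >= white_thresh &
      x[, , 3] >= white_thresh
    if (mean(white) < min_frac) {
      stop("no sufficiently large near-white region found; ",
           "supply a manual crop rectangle via `rect`")
    }
    lab <- label_components(white, connectivity = 8L)
    biggest <- which.max(tabulate(lab$labels[lab$labels > 0]))
    sel <- which(lab$labels == biggest, arr.ind = TRUE)
    rect <- c(min(sel[, 1]), max(sel[, 1]), min(sel[, 2]), max(sel[, 2]))
  }
  list(image = x[rect[1]:rect[2], rect[3]:rect[4], , drop = FALSE],
       rect = rect)
}

# Label connected components of a logical mask. Returns an integer matrix
# of labels (0 = background) and nothing else; sizes come from tabulate().
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(list(labels = labels, n = 0L))
  nr <- nrow(mask)
  pos <- match(idx, idx)  # identity; vertex ids are seq_along(idx)
  lut <- integer(length(mask)); lut[idx] <- seq_along(idx)
  edges <- integer(0)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  for (off in offs) {
    r2 <- ri + off[1]; c2 <- ci + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    nidx <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- lut[nidx] > 0L
    from <- lut[idx[ok]][ok2]
    to <- lut[nidx[ok2]]
    edges <- c(edges, rbind(from, to))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, n = comp$no)
}

#' Initial HSV mask
#'
#' Keeps a pixel iff its hue lies in either configured hue interval AND its
#' saturation and value lie in their intervals, all bounds inclusive.
#'
#' @param hsv H x W x 3 HSV array from [rgb_to_hsv()].
#' @param params A [mask_params()].
#' @return Logical H x W matrix.
#' @export
initial_mask <- function(hsv, params = mask_params()) {
  d <- dim(hsv)
  h <- matrix(hsv[, , 1], d[1], d[2])
  s <- matrix(hsv[, , 2], d[1], d[2])
  v <- matrix(hsv[, , 3], d[1], d[2])
  keep_h <- matrix(FALSE, nrow(h), ncol(h))
  for (i in seq_len(nrow(params$hue_ranges))) {
    keep_h <- keep_h | (h >= params$hue_ranges[i, 1] &
                          h <= params$hue_ranges[i, 2])
  }
  keep_h &
    s >= params$sat_range[1] & s <= params$sat_range[2] &
    v >= params$val_range[1] & v <= params$val_range[2]
}

#' Remove small connected components
#'
#' Components with strictly fewer than \code{min_component_px} pixels are
#' removed; components at or above the threshold are kept.
#'
#' @param mask Logical matrix.
#' @param min_component_px Size threshold.
#' @param connectivity 4 or 8.
#' @return Logical matrix.
#' @export
filter_small_components <- function(mask, min_component_px = 100L,
                                    connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (lab$n == 0L) return(mask)
  sizes <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
  keep <- which(sizes >= min_component_px)
  lab$labels %in% keep & mask
}

#' Refine a mask with region-based active contours
#'
#' Chan-Vese-style evolution with zero smoothing weight on the image's
#' value (brightness) channel: each sweep recomputes the inside/outside
#' mean intensities and flips boundary pixels to whichever region's mean is
#' closer. The contour can both grow and shrink, one pixel ring per sweep;
#' it stops early at a fixed point. A mask that already separates a
#' two-level image is unchanged.
#'
#' @param img [rgb_image()] or H x W x 3 array (RGB).
#' @param mask Non-empty logical matrix initialising the contour.
#' @param iterations Number of sweeps; 0 returns the mask unchanged.
#' @return Logical matrix.
#' @export
refine_active_contour <- function(img, mask, iterations = 50L) {
  x <- image_data(img)
  stopifnot(is.logical(mask), all(dim(mask) == dim(x)[1:2]))
  if (iterations == 0L) return(mask)
  if (!any(mask)) stop("cannot initialise active contour from an empty mask")
  v <- pmax(x[, , 1], pmax(x[, , 2], x[, , 3]))  # HSV value channel
  for (it in seq_len(iterations)) {
    if (!any(mask) || all(mask)) break
    c1 <- mean(v[mask]); c2 <- mean(v[!mask])
    nb <- neighbor_count(mask)
    boundary <- (mask & nb < 4L) | (!mask & nb > 0L)
    want_in <- (v - c1)^2 < (v - c2)^2
    newmask <- mask
    newmask[boundary] <- want_in[boundary]
    if (identical(newmask, mask)) break
    mask <- newmask
  }
  mask
}

# Number of TRUE 4-neighbours of every pixel (edges treated as FALSE).
neighbor_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr, nc)
  m[-1, ] <- m[-1, ] + mask[-nr, ]
  m[-nr, ] <- m[-nr, ] + mask[-1, ]
  m[, -1] <- m[, -1] + mask[, -nc]
  m[, -nc] <- m[, -nc] + mask[, -1]
  m
}

#' Saturation re-gate
#'
#' Intersects a mask with the pixels whose saturation lies in
#' \code{refine_sat_range} (inclusive). The result is always a subset of
#' the input mask.
#'
#' @param mask Logical matrix.
#' @param hsv HSV array matching the mask.
#' @param refine_sat_range Closed interval.
#' @return Logical matrix.
#' @export
refine_saturation <- function(mask, hsv, refine_sat_range = c(0.25, 1)) {
  s <- hsv[, , 2]
  stopifnot(all(dim(mask) == dim(s)))
  mask & s >= refine_sat_range[1] & s <= refine_sat_range[2]
}

#' Segment leaf pixels from a corrected RGB image
#'
#' Full masking chain: crop to the white background, convert to HSV, apply
#' the initial hue/saturation/value gate, drop small components, refine
#' with active contours, re-gate on saturation, and extract the surviving
#' pixels' coordinates (in the original, uncropped frame) and RGB values.
#' An image with no surviving pixels yields a flagged empty record rather
#' than an error, so batch runs survive failed plants.
#'
#' @param img Corrected [rgb_image()] or H x W x 3 array.
#' @param params A [mask_params()].
#' @param crop_rect Optional manual crop rectangle.
#' @return List of class \code{leaf_pixels}: \code{mask} (full-frame
#'   logical), \code{pixels} (data frame row, col, r, g, b), \code{empty}
#'   flag, \code{crop_rect}, and \code{stage_sizes} (pixel counts after
#'   each stage, the segmentation funnel).
#' @export
segment_leaves <- function(img, params = mask_params(), crop_rect = NULL) {
  x <- image_data(img)
  cr <- crop_to_white_background(x, rect = crop_rect)
  hsv <- rgb_to_hsv(cr$image)
  m0 <- initial_mask(hsv, params)
  m1 <- filter_small_components(m0, params$min_component_px,
                                params$connectivity)
  if (any(m1)) {
    m2 <- refine_active_contour(cr$image, m1, params$ac_iterations)
  } else {
    m2 <- m1
  }
  m3 <- refine_saturation(m2, hsv, params$refine_sat_range)

  full <- matrix(FALSE, dim(x)[1], dim(x)[2])
  full[cr$rect[1]:cr$rect[2], cr$rect[3]:cr$rect[4]] <- m3
  sel <- which(full, arr.ind = TRUE)
  if (nrow(sel)) {
    pixels <- data.frame(row = sel[, 1], col = sel[, 2],
                         r = x[cbind(sel, 1L)], g = x[cbind(sel, 2L)],
                         b = x[cbind(sel, 3L)])
  } else {
    pixels <- data.frame(row = integer(0), col = integer(0),
                         r = numeric(0), g = numeric(0), b = numeric(0))
  }
  structure(list(mask = full, pixels = pixels, empty = nrow(pixels) == 0L,
                 crop_rect = cr$rect,
                 stage_sizes = c(initial = sum(m0), filtered = sum(m1),
                                 grown = sum(m2), refined = sum(m3))),
            class = "leaf_pixels")
}
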