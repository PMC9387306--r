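#' Write a CFA frame as 16-bit TIFF plus JSON sidecar
#'
#' The sensor counts are stored in a single-channel 16-bit TIFF (scaled by
#' 1/65535, so integer counts up to 65535 round-trip exactly) and the
#' camera metadata (pattern, black/white level, gains, camera matrix, and
#' optionally the chart corner coordinates) in a JSON sidecar next to it.
#'
#' @param cfa A raw [cfa_image()].
#' @param tiff_path,json_path Output paths; \code{json_path} defaults to
#'   \code{tiff_path} with a \code{.json} extension.
#' @param chart_corners Optional 4 x 2 corner matrix to record.
#' @return Invisibly, the two paths.
#' @export
write_cfa <- function(cfa, tiff_path, json_path = NULL, chart_corners = NULL) {
  stopifnot(inherits(cfa, "cfa_image"), !cfa$normalized)
  if (is.null(json_path)) json_path <- sub("\\.tiff?$", ".json", tiff_path)
  if (cfa$white_level > 65535) stop("white level exceeds the 16-bit container")
  tiff::writeTIFF(cfa$data / 65535, tiff_path, bits.per.sample = 16L)
  meta <- list(bayer_pattern = cfa$pattern,
               black_level = cfa$black_level,
               white_level = cfa$white_level,
               wb_gains = as.list(cfa$wb_gains),
               camera_matrix = cfa$camera_matrix)
  if (!is.null(chart_corners)) meta$chart_corners <- unname(as.matrix(chart_corners))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff = tiff_path, json = json_path))
}

#' Read a CFA frame written by [write_cfa()]
#'
#' @param tiff_path,json_path Paths to the TIFF and its sidecar.
#' @return List with \code{cfa} (a [cfa_image()]) and \code{chart_corners}
#'   (4 x 2 matrix or \code{NULL}).
#' @export
read_cfa <- function(tiff_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.tiff?$", ".json", tiff_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  counts <- round(tiff::readTIFF(tiff_path) * 65535)
  cfa <- cfa_image(counts, pattern = meta$bayer_pattern,
                   black_level = meta$black_level,
                   white_level = meta$white_level,
                   wb_gains = c(r = meta$wb_gains$r, b = meta$wb_gains$b),
                   camera_matrix = matrix(unlist(meta$camera_matrix), 3, 3))
  corners <- if (!is.null(meta$chart_corners)) {
    matrix(unlist(meta$chart_corners), ncol = 2)
  }
  list(cfa = cfa, chart_corners = corners)
}

#' Write a binary mask as PNG (0/255)
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write an RGB image as 8-bit PNG
#' @param img [rgb_image()] or H x W x 3 array in [0, 1].
#' @param path Output path.
#' @export
write_rgb_png <- function(img, path) {
  png::writePNG(clip01(image_data(img)), path)
  invisible(path)
}
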