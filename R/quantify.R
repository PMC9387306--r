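#' Median RGB of a leaf-pixel set
#'
#' Per-channel independent medians (even counts use the midpoint of the two
#' central order statistics, the standard sample median). An empty pixel
#' set yields a missing-value triple rather than an error.
#'
#' @param pixels A \code{leaf_pixels} object from [segment_leaves()], or a
#'   data frame / matrix with columns r, g, b.
#' @return Named numeric vector \code{c(r, g, b)}; all \code{NA} when the
#'   pixel set is empty.
#' @export
median_rgb <- function(pixels) {
  if (inherits(pixels, "leaf_pixels")) pixels <- pixels$pixels
  if (is.data.frame(pixels)) {
    pixels <- as.matrix(pixels[, intersect(c("r", "g", "b"), names(pixels))])
  }
  if (is.null(dim(pixels)) || nrow(pixels) == 0L) {
    return(c(r = NA_real_, g = NA_real_, b = NA_real_))
  }
  c(r = stats::median(pixels[, 1]), g = stats::median(pixels[, 2]),
    b = stats::median(pixels[, 3]))
}

#' Join phenotype records to imaging medians
#'
#' Matches one leaf-pixel set to every plant-harvest record by the key
#' \code{plant_id:harvest} and appends \code{median_r}, \code{median_g},
#' \code{median_b}. Plants whose masks came back empty carry missing
#' medians; their count is attached as attribute \code{"n_empty"} and they
#' are expected to be excluded from the PCA.
#'
#' @param records Phenotype data frame with \code{plant_id} and
#'   \code{harvest} columns (see [generate_phenotype_table()]).
#' @param pixel_sets Named list of \code{leaf_pixels} objects (or r/g/b
#'   data frames), names formatted \code{"<plant_id>:<harvest>"}.
#' @return \code{records} with median columns appended.
#' @export
build_color_table <- function(records, pixel_sets) {
  keys <- paste(records$plant_id, records$harvest, sep = ":")
  if (anyDuplicated(keys)) {
    stop("duplicate plant-harvest keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  missing_keys <- setdiff(keys, names(pixel_sets))
  extra_keys <- setdiff(names(pixel_sets), keys)
  if (length(missing_keys) || length(extra_keys)) {
    stop("unmatched plant-harvest keys; missing pixel sets: [",
         paste(missing_keys, collapse = ", "), "], unmatched pixel sets: [",
         paste(extra_keys, collapse = ", "), "]")
  }
  med <- t(vapply(pixel_sets[keys], median_rgb, numeric(3)))
  records$median_r <- med[, 1]
  records$median_g <- med[, 2]
  records$median_b <- med[, 3]
  attr(records, "n_empty") <- sum(is.na(med[, 1]))
  records
}

#' Uncentered, unscaled principal component analysis
#'
#' Singular value decomposition of the raw n x 3 median-RGB matrix with no
#' centering and no scaling, preserving the channels' relative values. The
#' share of variation per axis is the squared singular value over their
#' sum. Because median RGB is non-negative, the first axis is a size
#' (lightness) axis; its loadings are fixed all-positive, so larger PC1
#' scores are lighter leaves and smaller (or more negative) scores darker.
#' Remaining axes' signs are fixed by making their largest-magnitude
#' loading positive.
#'
#' @param X n x 3 numeric matrix (n >= 3, no missing values).
#' @return Object of class \code{pca_uncentered}: \code{loadings} (3 x 3,
#'   columns PC1-PC3, orthonormal), \code{singular_values},
#'   \code{variance_explained} (sums to 1), \code{scores} (n x 3).
#' @export
uncentered_pca <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; exclude empty-mask records")
  if (nrow(X) < 3L) stop("need at least 3 records for a 3-channel PCA")
  stopifnot(ncol(X) == 3L)
  sv <- svd(X)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d)
  # sign conventions: PC1 all-positive (size axis), others by dominant loading
  for (k in 1:3) {
    flip <- if (k == 1L) sum(loadings[, k]) < 0 else
      loadings[which.max(abs(loadings[, k])), k] < 0
    if (flip) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(loadings) <- list(c("r", "g", "b"), c("PC1", "PC2", "PC3"))
  colnames(scores) <- c("PC1", "PC2", "PC3")
  structure(list(loadings = loadings, singular_values = sv$d,
                 variance_explained = sv$d^2 / sum(sv$d^2),
                 scores = scores, n = nrow(X)),
            class = "pca_uncentered")
}

#' @export
print.pca_uncentered <- function(x, ...) {
  cat("Uncentered PCA of", x$n, "median-RGB records\n")
  cat("variance explained:",
      paste(sprintf("%s %.1f%%", colnames(x$loadings),
                    100 * x$variance_explained), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Project records onto a fitted color-intensity model
#'
#' Scores are \code{X \%*\% loadings}; scoring the training matrix
#' reproduces the model's stored scores, and with all three axes the
#' projection is lossless (\code{scores \%*\% t(loadings)} reconstructs X).
#'
#' @param model A [uncentered_pca()] fit.
#' @param X n x 3 matrix of median RGB.
#' @return n x 3 matrix of PC scores.
#' @export
score_records <- function(model, X) {
  stopifnot(inherits(model, "pca_uncentered"))
  X <- as.matrix(X)
  if (ncol(X) != 3L) stop("X must have 3 columns (median R, G, B)")
  X %*% model$loadings
}

#' Attach PC scores to a color table
#'
#' Fits the uncentered PCA on complete rows of the median-RGB columns and
#' appends PC1-PC3 score columns (missing for empty-mask rows).
#'
#' @param table Output of [build_color_table()].
#' @return List with \code{table} (scores appended) and \code{pca} (the
#'   [uncentered_pca()] model).
#' @export
score_color_table <- function(table) {
  X <- as.matrix(table[, c("median_r", "median_g", "median_b")])
  ok <- stats::complete.cases(X)
  model <- uncentered_pca(X[ok, , drop = FALSE])
  sc <- matrix(NA_real_, nrow(table), 3L,
               dimnames = list(NULL, c("PC1", "PC2", "PC3")))
  sc[ok, ] <- score_records(model, X[ok, , drop = FALSE])
  table$PC1 <- sc[, 1]; table$PC2 <- sc[, 2]; table$PC3 <- sc[, 3]
  list(table = table, pca = model)
}
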