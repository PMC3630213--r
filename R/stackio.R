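# Image stacks and physical calibration.
#
# Conventions used throughout the package: pixel coordinates are 0-based,
# (x = column, y = row), pixel-centered; z index 0 is the first acquired
# slice. Stack arrays are indexed [row, col, slice].

#' Construct an image stack
#'
#' An `image_stack` holds a focus series as a 3D array of intensities in
#' `[0, 1]` indexed `[row (y), col (x), slice (z)]`, together with its
#' physical calibration.
#'
#' @param data numeric 3D array `(H, W, n_slices)`, or a list of equally
#'   sized matrices (slices in acquisition order).
#' @param calibration a [calibration()] object, or `NULL`.
#' @param normalize min-max normalize intensities to `[0, 1]` per stack
#'   (default `TRUE`). Sharpness comparisons are within-stack only, so the
#'   absolute intensity scale carries no information.
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, calibration = NULL, normalize = TRUE) {
  if (is.list(data)) {
    dims <- vapply(data, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all slices must have identical dimensions")
    data <- array(unlist(data), dim = c(dims[1, 1], dims[2, 1], length(data)))
  }
  if (length(dim(data)) != 3) stop("stack data must be a 3D array")
  if (dim(data)[3] < 2) stop("an image stack needs at least 2 slices")
  if (!all(is.finite(data))) stop("stack intensities must be finite")
  data <- data * 1.0
  if (normalize) {
    rng <- range(data)
    data <- if (rng[2] > rng[1]) (data - rng[1]) / (rng[2] - rng[1]) else data * 0
  }
  structure(
    list(data = data, n_slices = dim(data)[3],
         shape = dim(data)[1:2], calibration = calibration),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d x %d px, %d slices\n",
              x$shape[1], x$shape[2], x$n_slices))
  if (!is.null(x$calibration))
    cat(sprintf("  calibration: %.4g um/px, %.4g um/slice\n",
                x$calibration$um_per_px, x$calibration$um_per_slice))
  invisible(x)
}

#' Physical calibration of a stack
#'
#' @param um_per_px lateral scale, micrometres per pixel (from a scaling
#'   slide; user supplied).
#' @param um_per_slice axial scale, micrometres per z-slice. Usually derived
#'   with [calibrate_z()] from a reference object of known thickness imaged
#'   next to the leaf.
#' @return a `calibration` object.
#' @export
calibration <- function(um_per_px, um_per_slice) {
  if (!is.finite(um_per_px) || um_per_px <= 0)
    stop("um_per_px must be positive and finite")
  if (!is.finite(um_per_slice) || um_per_slice <= 0)
    stop("um_per_slice must be positive and finite")
  structure(list(um_per_px = um_per_px, um_per_slice = um_per_slice),
            class = "calibration")
}

#' Axial calibration from a reference object of known thickness
#'
#' A cover-slide fragment of known thickness is placed next to the specimen;
#' the slice indices at which its bottom and top surfaces are in focus span
#' the reference thickness, giving micrometres per z-slice.
#'
#' @param ref_thickness_um reference thickness in micrometres (> 0).
#' @param idx_bottom,idx_top slice indices of the in-focus bottom and top
#'   surfaces (order irrelevant).
#' @return micrometres per slice.
#' @examples
#' calibrate_z(170, 0, 50)  # 3.4 um/slice
#' @export
calibrate_z <- function(ref_thickness_um, idx_bottom, idx_top) {
  if (!is.finite(ref_thickness_um) || ref_thickness_um <= 0)
    stop("ref_thickness_um must be positive")
  if (idx_bottom == idx_top)
    stop("calibration error: idx_bottom and idx_top are equal (zero axial extent)")
  ref_thickness_um / abs(idx_top - idx_bottom)
}

#' Read an image stack from TIFF file(s)
#'
#' Accepts a single multi-page TIFF or a character vector of single-page
#' TIFFs ordered by acquisition index (sorted lexicographically if unsorted
#' input is a directory listing). Only uncompressed grayscale 8/16-bit TIFF
#' is supported. Intensities are min-max normalized to `[0, 1]` per stack.
#'
#' @param paths one multi-page TIFF path, or several single-page TIFF paths.
#' @param calibration optional [calibration()] attached to the stack.
#' @return an [image_stack()].
#' @export
read_stack <- function(paths, calibration = NULL) {
  for (p in paths) if (!file.exists(p)) stop("stack file not found: ", p)
  pages <- list()
  for (p in paths) pages <- c(pages, read_tiff_gray(p)$pages)
  if (length(pages) < 2) stop("an image stack needs at least 2 slices")
  image_stack(lapply(pages, function(m) m * 1.0), calibration = calibration)
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities in `[0, 1]` are scaled to the full range of the requested bit
#' depth and rounded.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @param bits 8 or 16 (default 16).
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  top <- 2^bits - 1
  pages <- lapply(seq_len(stack$n_slices), function(k)
    matrix(as.integer(round(stack$data[, , k] * top)),
           nrow = stack$shape[1]))
  write_tiff_gray(pages, path, bits = bits)
}

#' Write a 2D image (matrix of intensities in 0..1) as grayscale TIFF
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path.
#' @param bits 8 or 16.
#' @export
write_image <- function(img, path, bits = 16L) {
  top <- 2^bits - 1
  write_tiff_gray(matrix(as.integer(round(img * top)), nrow = nrow(img)),
                  path, bits = bits)
}
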