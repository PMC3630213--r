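# Shape-from-focus: Sobel sharpness, height-map extraction, sharp-image
# composition.

# Shift a matrix or 3D array by (dy, dx) with edge replication.
shift_img <- function(a, dy, dx) {
  d <- dim(a)
  ri <- pmin(pmax(seq_len(d[1]) + dy, 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2]) + dx, 1L), d[2])
  if (length(d) == 3) a[ri, ci, , drop = FALSE] else a[ri, ci, drop = FALSE]
}

#' Per-slice Sobel sharpness of an image stack
#'
#' Sharpness of each slice is the magnitude of its Sobel gradient,
#' `sqrt(Gx^2 + Gy^2)`, with the standard 3x3 kernel pair and edge-replicated
#' borders. In a focus series, high Sobel magnitude marks in-focus texture.
#'
#' @param stack an [image_stack()], or a single 2D matrix.
#' @return array of the same dimensions with non-negative sharpness values.
#' @export
sobel_sharpness <- function(stack) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  s <- function(dy, dx) shift_img(a, dy, dx)
  # correlation with [-1 0 1; -2 0 2; -1 0 1] (x = columns) and its transpose
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) - (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) - (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  sqrt(gx^2 + gy^2)
}

# Separable square maximum filter with edge replication; w odd.
max_filter <- function(a, w) {
  r <- (w - 1L) %/% 2L
  out <- a
  for (dx in setdiff(-r:r, 0L)) out <- pmax(out, shift_img(a, 0L, dx))
  a2 <- out
  for (dy in setdiff(-r:r, 0L)) out <- pmax(out, shift_img(a2, dy, 0L))
  out
}

#' Extract the height map (best-focus z per pixel) from a focus stack
#'
#' For every pixel the sharpness of each slice is aggregated over a
#' `window x window` neighborhood (maximum filter) and the slice maximizing
#' the aggregate is taken as the pixel's height. Ties are broken toward the
#' lowest slice index. Pixels with no texture in any slice (aggregate
#' sharpness below `texture_eps` everywhere) take the height of the nearest
#' textured pixel.
#'
#' @param stack an [image_stack()].
#' @param window odd neighborhood size for sharpness aggregation (default 5).
#' @param texture_eps sharpness level below which a pixel counts as
#'   textureless (default `1e-6` on `[0,1]`-normalized intensities).
#' @return a `height_map` object: `z_index` (0-based slice indices, H x W),
#'   `z_um` (if the stack is calibrated), `textured` (logical H x W), and the
#'   calibration.
#' @export
compute_height_map <- function(stack, window = 5L, texture_eps = 1e-6) {
  stopifnot(inherits(stack, "image_stack"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  H <- stack$shape[1]; W <- stack$shape[2]; n <- stack$n_slices
  agg <- max_filter(sobel_sharpness(stack), window)
  m <- matrix(agg, H * W, n)
  peak <- do.call(pmax, lapply(seq_len(n), function(k) m[, k]))
  z <- max.col(m, ties.method = "first") - 1L   # 0-based; ties -> lowest slice
  textured <- matrix(peak >= texture_eps, H, W)
  zi <- matrix(z, H, W)
  if (!all(textured)) {
    if (!any(textured)) {
      zi[] <- 0L  # fully textureless stack: flat fallback
    } else {
      zi <- nearest_fill(zi, textured)
    }
  }
  structure(
    list(z_index = zi,
         z_um = if (!is.null(stack$calibration))
           zi * stack$calibration$um_per_slice,
         textured = textured,
         calibration = stack$calibration,
         n_slices = n),
    class = "height_map"
  )
}

# Fill values at !known pixels from the nearest known pixel by iterative
# 4-neighbor propagation (ties resolved by sweep order: up, down, left, right).
nearest_fill <- function(z, known) {
  while (!all(known)) {
    progressed <- FALSE
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      kz <- shift_img(z, d[1], d[2])
      kk <- shift_img(known, d[1], d[2])
      take <- !known & kk
      if (any(take)) {
        z[take] <- kz[take]
        known <- known | take
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  z
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d px, z in [%d, %d] of %d slices\n",
              nrow(x$z_index), ncol(x$z_index),
              min(x$z_index), max(x$z_index), x$n_slices))
  invisible(x)
}

#' Compose the all-in-focus 2D image from a stack and its height map
#'
#' Every output pixel takes the intensity of the slice named by the height
#' map at that position.
#'
#' @param stack an [image_stack()].
#' @param hm a `height_map` from [compute_height_map()] (same H x W).
#' @return numeric H x W matrix in `[0, 1]` (a sharp image).
#' @export
compose_sharp_image <- function(stack, hm) {
  stopifnot(inherits(stack, "image_stack"), inherits(hm, "height_map"))
  H <- stack$shape[1]; W <- stack$shape[2]
  if (!all(dim(hm$z_index) == c(H, W)))
    stop("dimension error: height map does not match stack shape")
  idx <- seq_len(H * W) + as.vector(hm$z_index) * (H * W)
  matrix(stack$data[idx], H, W)
}

#' Export a height map as CSV (long form) or 16-bit TIFF of z indices
#' @param hm a `height_map`.
#' @param path output path; `.csv` writes columns x_px, y_px, z_index
#'   (0-based), otherwise a 16-bit TIFF of z indices is written.
#' @export
write_height_map <- function(hm, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    H <- nrow(hm$z_index); W <- ncol(hm$z_index)
    df <- data.frame(
      x_px = rep(0:(W - 1), each = H),
      y_px = rep(0:(H - 1), times = W),
      z_index = as.vector(hm$z_index)
    )
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    write_tiff_gray(matrix(as.integer(hm$z_index), nrow(hm$z_index)),
                    path, bits = 16L)
  }
  invisible(path)
}
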