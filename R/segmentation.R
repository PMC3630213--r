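# Leaf segmentation: Otsu thresholding, disc opening, hole filling, boundary
# tracing; manual convex-hull fallback.

#' Otsu threshold of a grayscale image
#'
#' Returns the histogram threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. Ties break toward the lower threshold.
#'
#' @param img numeric matrix (or vector) of intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return threshold value; pixels `<= threshold` form the lower class.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(img)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate input: constant image has no Otsu threshold")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  bin <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  vsum <- rep(0, n_bins)
  agg <- rowsum(v, bin)
  vsum[as.integer(rownames(agg))] <- agg[, 1]
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu <- cumsum(vsum) / sum(counts)   # exact class-mean numerators
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  # between-class variance at a cut after each bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1L)
  num <- (mu_t * w0[k] - mu[k])^2
  den <- w0[k] * w1[k]
  crit <- ifelse(den > 0, num / den, -Inf)
  best <- which.max(crit)   # ties -> lowest cut
  edges[best + 1L]          # upper edge of the last lower-class bin
}

# --- small morphology / labeling toolkit (no morphology package available) ---

disc_kernel <- function(radius) {
  r <- as.integer(radius)
  d <- 2L * r + 1L
  xs <- matrix(rep(-r:r, each = d), d, d)
  ys <- t(xs)
  (xs^2 + ys^2 <= r^2 + 1e-9) * 1
}

# 2D "same" convolution via FFT (kernel dims odd).
conv2d_same <- function(img, ker) {
  H <- nrow(img); W <- ncol(img); kh <- nrow(ker); kw <- ncol(ker)
  PH <- H + kh - 1L; PW <- W + kw - 1L
  A <- matrix(0, PH, PW); A[1:H, 1:W] <- img
  K <- matrix(0, PH, PW); K[1:kh, 1:kw] <- ker
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (PH * PW)
  ro <- (kh - 1L) %/% 2L; co <- (kw - 1L) %/% 2L
  full[(ro + 1L):(ro + H), (co + 1L):(co + W)]
}

erode_disc <- function(mask, radius) {
  ker <- disc_kernel(radius)
  conv2d_same(mask * 1, ker) >= sum(ker) - 0.5
}

dilate_disc <- function(mask, radius) {
  conv2d_same(mask * 1, disc_kernel(radius)) >= 0.5
}

#' Binary opening by a disc structuring element
#' @param mask logical matrix.
#' @param radius disc radius in pixels.
#' @return logical matrix; always a subset of `mask` (anti-extensive).
#' @export
open_disc <- function(mask, radius) {
  dilate_disc(erode_disc(mask, radius), radius) & mask
}

# Label 4-connected components; returns integer matrix (0 = background).
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (!length(idx)) return(lab)
  pos <- match(seq_len(H * W), idx)   # linear index -> vertex id
  edges <- integer(0)
  right <- idx[idx + H <= H * W & mask[pmin(idx + H, H * W)]]
  right <- right[mask[right]]
  down <- idx[(idx %% H) != 0 & mask[pmin(idx + 1L, H * W)]]
  if (length(right)) edges <- c(edges, rbind(pos[right], pos[right + H]))
  if (length(down)) edges <- c(edges, rbind(pos[down], pos[down + 1L]))
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  lab == which.max(tabulate(lab[lab > 0L]))
}

# Fill holes: background components not touching the image border.
fill_holes <- function(mask) {
  lab <- label_components(!mask)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

# Trace the outer boundary of a (single-component, hole-free) mask as a closed
# polygon in 0-based (x, y) pixel coordinates, via the 0.5 contour.
trace_boundary <- function(mask) {
  cl <- grDevices::contourLines(x = 0:(ncol(mask) - 1), y = 0:(nrow(mask) - 1),
                                z = t(mask * 1), levels = 0.5)
  if (!length(cl)) stop("segmentation failure: no boundary found")
  lens <- vapply(cl, function(c) length(c$x), numeric(1))
  b <- cl[[which.max(lens)]]
  cbind(x = b$x, y = b$y)
}

#' Construct a leaf mask from a logical matrix
#'
#' Usually produced by [segment_leaf()] or [manual_leaf_polygon()]; the
#' constructor is exported for synthetic masks. The boundary polygon is
#' traced from the mask's 0.5-level contour unless supplied.
#'
#' @param mask logical H x W matrix.
#' @param boundary optional boundary polygon ((x, y) rows, 0-based pixels).
#' @return a `leaf_mask` (`mask`, `boundary`, `area_px`).
#' @export
leaf_mask <- function(mask, boundary = NULL) {
  structure(list(mask = mask,
                 boundary = if (is.null(boundary)) trace_boundary(mask) else boundary,
                 area_px = sum(mask)),
            class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %d x %d px, area %d px\n",
              nrow(x$mask), ncol(x$mask), x$area_px))
  invisible(x)
}

#' Segment the leaf in a sharp image
#'
#' Otsu-thresholds the image (leaf assumed darker than background by default,
#' as in bright-field microscopy), keeps the largest connected component,
#' removes trichomes protruding over the outline by morphological opening
#' with a disc larger than the broadest trichome, fills holes, and traces the
#' boundary.
#'
#' @param img numeric H x W matrix in `[0, 1]` (a sharp image).
#' @param disc_radius_px opening disc radius in pixels; choose it larger than
#'   the broadest trichome (default 25).
#' @param polarity `"dark"` if the leaf is darker than the background
#'   (default), `"light"` otherwise.
#' @param fill fill holes after opening (default `TRUE`).
#' @return a `leaf_mask` object (`mask`, `boundary` polygon, `area_px`).
#' @export
segment_leaf <- function(img, disc_radius_px = 25L, polarity = c("dark", "light"),
                         fill = TRUE) {
  polarity <- match.arg(polarity)
  if (disc_radius_px < 1) stop("disc_radius_px must be >= 1")
  thr <- otsu_threshold(img)
  fg <- if (polarity == "dark") img <= thr else img > thr
  if (!any(fg)) stop("segmentation failure: empty foreground after thresholding")
  fg <- largest_component(fg)
  fg <- open_disc(fg, disc_radius_px)
  if (!any(fg)) stop("segmentation failure: empty foreground after opening")
  fg <- largest_component(fg)
  if (fill) fg <- fill_holes(fg)
  leaf_mask(fg)
}

# Rasterize a convex polygon ((x, y) 0-based pixel coordinates): a pixel
# belongs if its center lies inside or on the boundary.
rasterize_convex <- function(poly, shape) {
  H <- shape[1]; W <- shape[2]
  mask <- matrix(FALSE, H, W)
  eps <- 1e-9
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  for (y in 0:(H - 1)) {
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- py[i]; y2 <- py[j]
      if (abs(y1 - y2) < eps) {
        if (abs(y - y1) < eps) xs <- c(xs, px[i], px[j])
      } else if (y >= min(y1, y2) - eps && y <= max(y1, y2) + eps) {
        t <- (y - y1) / (y2 - y1)
        t <- min(max(t, 0), 1)
        xs <- c(xs, px[i] + t * (px[j] - px[i]))
      }
    }
    if (!length(xs)) next
    x0 <- ceiling(min(xs) - eps); x1 <- floor(max(xs) + eps)
    if (x1 >= x0) {
      cols <- max(x0, 0L):min(x1, W - 1L)
      if (length(cols) && cols[1] <= cols[length(cols)])
        mask[y + 1L, cols + 1L] <- TRUE
    }
  }
  mask
}

#' Leaf mask from a manually drawn outline (convex hull)
#'
#' Builds the mask as the rasterized convex hull of the supplied points: a
#' pixel belongs if its center is inside or on the hull boundary.
#'
#' @param points numeric matrix/data frame with columns (x, y) in 0-based
#'   pixel coordinates; at least 3 non-collinear points.
#' @param shape output `(H, W)`; defaults to the hull's bounding box.
#' @return a `leaf_mask`.
#' @export
manual_leaf_polygon <- function(points, shape = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 3) stop("geometry error: need at least 3 points")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  if (nrow(hull) < 3 || abs(polygon_area(hull)) < 1e-12)
    stop("geometry error: points are collinear")
  if (is.null(shape))
    shape <- c(ceiling(max(pts[, 2])) + 1L, ceiling(max(pts[, 1])) + 1L)
  mask <- rasterize_convex(hull, shape)
  leaf_mask(mask, boundary = rbind(hull, hull[1, , drop = FALSE]))
}

# Shoelace area of a polygon given as (x, y) rows (open or closed).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Export a leaf mask: boundary polygon as CSV, mask as 8-bit TIFF
#' @param lm a `leaf_mask`.
#' @param path output path; `.csv` writes the boundary vertices (x, y),
#'   otherwise a binary 8-bit TIFF (0/255) is written.
#' @export
write_leaf_mask <- function(lm, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(data.frame(x = lm$boundary[, 1], y = lm$boundary[, 2]),
                     path, row.names = FALSE)
  } else {
    write_tiff_gray(matrix(as.integer(lm$mask) * 255L, nrow(lm$mask)),
                    path, bits = 8L)
  }
  invisible(path)
}
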