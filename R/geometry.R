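# Distances (2D/3D Euclidean, geodesic), areas, per-triangle distortion, and
# Voronoi tessellations on the reconstructed surface.

#' 2D Euclidean distance
#' @param p,q numeric `(x, y)` vectors or 2-column matrices (micrometres).
#' @return distance(s) in micrometres.
#' @export
dist2d <- function(p, q) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  if (is.null(dim(q))) q <- matrix(q, ncol = 2)
  out <- sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2)
  if (length(out) == 1) out[[1]] else out
}

#' 3D Euclidean distance with heights from the elastic map
#'
#' The z coordinate of each point is `evaluate_surface(map, .)`; always
#' `>= dist2d(p, q)`.
#'
#' @param p,q `(x, y)` points (micrometres) inside the map domain.
#' @param map an `elastic_map`.
#' @export
dist3d <- function(p, q, map) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  if (is.null(dim(q))) q <- matrix(q, ncol = 2)
  zp <- evaluate_surface(map, p)
  zq <- evaluate_surface(map, q)
  out <- sqrt((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2 + (zp - zq)^2)
  if (length(out) == 1) out[[1]] else out
}

# ---- surface points and point location -------------------------------------

# Locate (x, y) queries on the mesh's grid triangulation. Returns a list with
# triangle indices and barycentric coordinates; errors for points in removed
# or out-of-range cells.
mesh_locate <- function(mesh, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  g <- mesh$grid
  if (is.null(g))
    stop("mesh has no grid information; point location needs a triangulate()d elastic map")
  nx <- g$node_x; ny <- g$node_y
  n1 <- g$n - 1L; m1 <- g$m - 1L
  j <- pmin(pmax(findInterval(xy[, 1], nx), 1L), m1)
  i <- pmin(pmax(findInterval(xy[, 2], ny), 1L), n1)
  cell <- i + (j - 1L) * n1
  keep_pos <- cumsum(g$cell_keep)
  if (any(!g$cell_keep[cell]))
    stop("surface point lies outside the meshed region")
  pos <- keep_pos[cell]
  K <- sum(g$cell_keep)
  V <- mesh$vertices
  tri <- integer(nrow(xy)); bary <- matrix(0, nrow(xy), 3)
  for (r in seq_len(nrow(xy))) {
    for (cand in c(pos[r], K + pos[r])) {
      tv <- mesh$triangles[cand, ]
      b <- bary_coords(xy[r, ], V[tv, 1], V[tv, 2])
      if (all(b >= -1e-9)) { tri[r] <- cand; bary[r, ] <- pmax(b, 0); break }
    }
    if (tri[r] == 0L) { # numeric edge case: fall back to first candidate
      tri[r] <- pos[r]
      tv <- mesh$triangles[tri[r], ]
      b <- bary_coords(xy[r, ], V[tv, 1], V[tv, 2])
      bary[r, ] <- pmax(b, 0); bary[r, ] <- bary[r, ] / sum(bary[r, ])
    }
  }
  list(tri = tri, bary = bary)
}

bary_coords <- function(p, tx, ty) {
  d <- (ty[2] - ty[3]) * (tx[1] - tx[3]) + (tx[3] - tx[2]) * (ty[1] - ty[3])
  l1 <- ((ty[2] - ty[3]) * (p[1] - tx[3]) + (tx[3] - tx[2]) * (p[2] - ty[3])) / d
  l2 <- ((ty[3] - ty[1]) * (p[1] - tx[3]) + (tx[1] - tx[3]) * (p[2] - ty[3])) / d
  c(l1, l2, 1 - l1 - l2)
}

#' Lift (x, y) positions onto the mesh surface
#' @param mesh a `surface_mesh`.
#' @param xy `(x, y)` vector or 2-column matrix (micrometres).
#' @return matrix of 3D positions (rows match `xy`).
#' @export
lift_to_mesh <- function(mesh, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  loc <- mesh_locate(mesh, xy)
  V <- mesh$vertices
  out <- matrix(0, nrow(xy), 3)
  for (r in seq_len(nrow(xy))) {
    tv <- mesh$triangles[loc$tri[r], ]
    out[r, ] <- colSums(loc$bary[r, ] * V[tv, , drop = FALSE])
  }
  out
}

#' Geodesic distance field from a surface point
#'
#' First-order eikonal solve (fast marching with Gauss-Seidel repair sweeps)
#' on the triangulated surface, seeded with exact distances on the source
#' point's triangle.
#'
#' @param mesh a `surface_mesh`.
#' @param source `(x, y)` of the source (micrometres).
#' @return numeric per-vertex geodesic distance (micrometres).
#' @export
geodesic_field <- function(mesh, source, init_rings = 8) {
  loc <- mesh_locate(mesh, matrix(source, ncol = 2))
  V <- mesh$vertices
  tv <- mesh$triangles[loc$tri[1], ]
  p3 <- colSums(loc$bary[1, ] * V[tv, , drop = FALSE])
  # Exact (straight-line) seeding inside a small disk around the source
  # removes the O(h) source-singularity error of the first-order solver; the
  # curvature error committed there is O((kh)^3 / r^2), negligible for any
  # surface whose curvature radius exceeds a few cell sizes.
  h <- mean(sqrt(rowSums((V[mesh$triangles[, 1], , drop = FALSE] -
                            V[mesh$triangles[, 2], , drop = FALSE])^2)))
  de <- sqrt((V[, 1] - p3[1])^2 + (V[, 2] - p3[2])^2 + (V[, 3] - p3[3])^2)
  init <- rep(Inf, nrow(V))
  seed <- de <= init_rings * h
  seed[tv] <- TRUE
  init[seed] <- de[seed]
  fast_march_cpp(V, mesh$triangles - 1L, init)
}

#' Geodesic distance between two surface points
#'
#' @param mesh a `surface_mesh`.
#' @param a,b `(x, y)` positions (micrometres) on the meshed region.
#' @return geodesic distance (micrometres).
#' @export
geodesic_distance <- function(mesh, a, b) {
  d <- geodesic_field(mesh, a)
  eval_field(mesh, d, b, a)
}

# Linear interpolation of a vertex field at point b; if a is supplied and
# shares b's triangle, the straight in-triangle distance is an exact lower
# candidate (handles a == b).
eval_field <- function(mesh, d, b, a = NULL) {
  loc <- mesh_locate(mesh, matrix(b, ncol = 2))
  tv <- mesh$triangles[loc$tri[1], ]
  if (any(!is.finite(d[tv])))
    stop("unreachable error: target lies in a disconnected mesh component")
  val <- sum(loc$bary[1, ] * d[tv])
  if (!is.null(a)) {
    la <- mesh_locate(mesh, matrix(a, ncol = 2))
    if (la$tri[1] == loc$tri[1]) {
      V <- mesh$vertices
      pa <- colSums(la$bary[1, ] * V[mesh$triangles[la$tri[1], ], , drop = FALSE])
      pb <- colSums(loc$bary[1, ] * V[tv, , drop = FALSE])
      val <- min(val, sqrt(sum((pa - pb)^2)))
    }
  }
  val
}

#' Geodesic nearest-neighbor distance for a set of surface points
#'
#' For each point, the minimum geodesic distance to any other point — on the
#' leaf a measure of the spatial inhibition between trichomes.
#'
#' @param mesh a `surface_mesh`.
#' @param points 2-column matrix / data frame of `(x, y)` (micrometres);
#'   at least 2 rows.
#' @return numeric vector of nearest-neighbor distances.
#' @export
geodesic_nn <- function(mesh, points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 2) stop("geodesic_nn needs at least 2 points")
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    f <- geodesic_field(mesh, pts[i, ])
    for (j in seq_len(n)) if (j != i)
      D[i, j] <- eval_field(mesh, f, pts[j, ], pts[i, ])
  }
  D <- pmin(D, t(D))  # enforce symmetry of the solver output
  apply(D, 1, min)
}

# ---- areas and distortion ---------------------------------------------------

#' Projected (2D) area of a leaf mask or polygon
#' @param x a `leaf_mask` or a polygon ((x, y) rows, micrometres).
#' @param um_per_px lateral scale, needed for masks (pixel count times
#'   `um_per_px^2`).
#' @return area in square micrometres.
#' @export
area2d <- function(x, um_per_px = 1) {
  if (inherits(x, "leaf_mask")) {
    if (x$area_px == 0) stop("empty region")
    return(x$area_px * um_per_px^2)
  }
  x <- as.matrix(x)
  a <- polygon_area(x)
  if (a == 0) stop("empty region: degenerate polygon")
  a
}

#' Surface (3D) area of a mesh, optionally restricted to a 2D region
#' @param mesh a `surface_mesh`.
#' @param region optional `leaf_mask`; triangles are kept when their (x, y)
#'   centroid (via `uv`) falls inside the mask.
#' @param um_per_px lateral scale used to map uv micrometres to mask pixels.
#' @return area in square micrometres; always >= the projected 2D area of the
#'   same triangles.
#' @export
area3d <- function(mesh, region = NULL, um_per_px = 1) {
  keep <- rep(TRUE, nrow(mesh$triangles))
  if (!is.null(region)) {
    cen <- tri_centroids_uv(mesh)
    col <- round(cen[, 1] / um_per_px) + 1L
    row <- round(cen[, 2] / um_per_px) + 1L
    H <- nrow(region$mask); W <- ncol(region$mask)
    inside <- col >= 1 & col <= W & row >= 1 & row <= H
    keep <- inside
    keep[inside] <- region$mask[cbind(row[inside], col[inside])]
  }
  sum(tri_areas_3d(mesh$vertices, mesh$triangles[keep, , drop = FALSE]))
}

tri_centroids_uv <- function(mesh) {
  (mesh$uv[mesh$triangles[, 1], , drop = FALSE] +
     mesh$uv[mesh$triangles[, 2], , drop = FALSE] +
     mesh$uv[mesh$triangles[, 3], , drop = FALSE]) / 3
}

tri_centroids_3d <- function(mesh) {
  (mesh$vertices[mesh$triangles[, 1], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 2], , drop = FALSE] +
     mesh$vertices[mesh$triangles[, 3], , drop = FALSE]) / 3
}

#' Per-triangle distortion (projected 2D area / 3D area)
#'
#' Distortion 1 means the triangle is parallel to the image plane; small
#' values mark steep leaf regions where flat-image measurements underestimate
#' true distances and areas. Also returns a longitudinal profile: the mean
#' ratio binned along the y axis with a 50% band (25th-75th percentile).
#'
#' @param mesh a `surface_mesh`.
#' @param n_bins bins of the longitudinal profile (default 20).
#' @return a `distortion_map`: tibble `triangles` (id, x, y, ratio) and
#'   tibble `profile` (bin center, mean, q25, q75, n).
#' @export
distortion_map <- function(mesh, n_bins = 20L) {
  a3 <- tri_areas_3d(mesh$vertices, mesh$triangles)
  if (any(a3 <= 0)) stop("mesh error: zero-area triangle")
  a2 <- abs(tri_areas_2d(mesh$vertices, mesh$triangles))
  ratio <- pmin(a2 / a3, 1)
  cen <- tri_centroids_uv(mesh)
  tri_tbl <- tibble::tibble(triangle = seq_along(ratio),
                            x = cen[, 1], y = cen[, 2], ratio = ratio)
  brk <- seq(min(cen[, 2]), max(cen[, 2]), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(cen[, 2], brk, rightmost.closed = TRUE), 1L),
              n_bins)
  prof <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, ratio = ratio), .data$bin),
    mean = mean(.data$ratio),
    q25 = stats::quantile(.data$ratio, 0.25, names = FALSE),
    q75 = stats::quantile(.data$ratio, 0.75, names = FALSE),
    n = dplyr::n(), .groups = "drop")
  prof$y <- (brk[prof$bin] + brk[prof$bin + 1L]) / 2
  structure(list(triangles = tri_tbl, profile = prof), class = "distortion_map")
}

#' @export
print.distortion_map <- function(x, ...) {
  cat(sprintf("<distortion_map> %d triangles, ratio in [%.3f, %.3f]\n",
              nrow(x$triangles), min(x$triangles$ratio), max(x$triangles$ratio)))
  invisible(x)
}

# ---- Voronoi ----------------------------------------------------------------

# Clip a polygon by the half-plane of points at least as close to p as to q.
clip_bisector <- function(poly, p, q) {
  dirx <- q[1] - p[1]; diry <- q[2] - p[2]
  mx <- (p[1] + q[1]) / 2; my <- (p[2] + q[2]) / 2
  f <- (poly[, 1] - mx) * dirx + (poly[, 2] - my) * diry
  clip_signed(poly, f)
}

# Sutherland-Hodgman step keeping vertices with f <= 0.
clip_signed <- function(poly, f) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  out <- matrix(0, 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- poly[i, ]; vj <- poly[j, ]
    ini <- f[i] <= 0; inj <- f[j] <= 0
    if (ini) out <- rbind(out, vi)
    if (xor(ini, inj)) {
      t <- f[i] / (f[i] - f[j])
      out <- rbind(out, vi + t * (vj - vi))
    }
  }
  out
}

# Intersect an arbitrary simple polygon with a convex polygon (CCW);
# area-exact even when the result is disconnected (zero-width bridges).
clip_to_convex <- function(subject, clipper) {
  # ensure CCW clipper
  x <- clipper[, 1]; y <- clipper[, 2]
  j <- c(2:nrow(clipper), 1L)
  if (sum(x * y[j] - x[j] * y) < 0) clipper <- clipper[nrow(clipper):1, ]
  poly <- subject
  for (i in seq_len(nrow(clipper))) {
    if (nrow(poly) == 0) break
    k <- if (i == nrow(clipper)) 1L else i + 1L
    a <- clipper[i, ]; b <- clipper[k, ]
    # inside = left of edge a->b for CCW clipper; keep f <= 0
    f <- -((b[1] - a[1]) * (poly[, 2] - a[2]) - (b[2] - a[2]) * (poly[, 1] - a[1]))
    poly <- clip_signed(poly, f)
  }
  poly
}

#' Planar Voronoi tessellation of trichome positions, clipped to the leaf
#'
#' Each generator's cell is the intersection of the bisector half-planes
#' against all other generators. Cells that are unbounded before clipping
#' (convex-hull generators, "marginal" trichomes) are flagged infinite and
#' excluded from area statistics; finite cells are clipped to the leaf
#' boundary polygon and their areas reported in square micrometres.
#'
#' @param points 2-column matrix / data frame of `(x, y)` in micrometres
#'   (>= 3 non-collinear points).
#' @param leaf a `leaf_mask`, or a boundary polygon ((x, y) rows) in
#'   micrometres.
#' @param um_per_px lateral scale converting a `leaf_mask`'s pixel boundary
#'   to micrometres (default 1).
#' @return tibble with `id`, `x`, `y`, `finite`, `area_um2` (NA when
#'   infinite) and `metric = "euclidean2d"`.
#' @export
voronoi_2d <- function(points, leaf, um_per_px = 1) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 3) stop("geometry error: Voronoi needs at least 3 points")
  cen <- scale(pts, scale = FALSE)
  if (min(svd(cen)$d) < 1e-9 * max(svd(cen)$d))
    stop("geometry error: points are collinear")
  poly_leaf <- if (inherits(leaf, "leaf_mask")) leaf$boundary * um_per_px
  else as.matrix(leaf)
  diam <- max(dist2d(matrix(apply(rbind(poly_leaf, pts), 2, min), ncol = 2),
                     matrix(apply(rbind(poly_leaf, pts), 2, max), ncol = 2)),
              1e-6)
  lo <- apply(rbind(poly_leaf, pts), 2, min) - 4 * diam
  hi <- apply(rbind(poly_leaf, pts), 2, max) + 4 * diam
  box <- rbind(c(lo[1], lo[2]), c(hi[1], lo[2]), c(hi[1], hi[2]), c(lo[1], hi[2]))
  eps <- 1e-7 * diam
  out <- tibble::tibble(id = seq_len(n), x = pts[, 1], y = pts[, 2],
                        finite = NA, area_um2 = NA_real_,
                        metric = "euclidean2d")
  for (i in seq_len(n)) {
    cell <- box
    for (k in seq_len(n)) {
      if (k == i || nrow(cell) == 0) next
      cell <- clip_bisector(cell, pts[i, ], pts[k, ])
    }
    unbounded <- nrow(cell) > 0 &&
      any(cell[, 1] < lo[1] + eps | cell[, 1] > hi[1] - eps |
            cell[, 2] < lo[2] + eps | cell[, 2] > hi[2] - eps)
    out$finite[i] <- !unbounded && nrow(cell) >= 3
    if (out$finite[i]) {
      clipped <- clip_to_convex(poly_leaf, cell)
      out$area_um2[i] <- if (nrow(clipped) >= 3) polygon_area(clipped) else 0
    }
  }
  out
}

# Boundary-touching flags per triangle: TRUE when the triangle owns an edge
# used by no other triangle.
boundary_triangles <- function(mesh) {
  Tm <- mesh$triangles
  e <- rbind(Tm[, c(1, 2)], Tm[, c(2, 3)], Tm[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  single <- cnt[key] == 1
  matrix(single, nrow(Tm), 3)[, 1] |
    matrix(single, nrow(Tm), 3)[, 2] |
    matrix(single, nrow(Tm), 3)[, 3]
}

#' Surface Voronoi tessellation by 3D Euclidean distance
#'
#' Every mesh triangle is assigned (via its centroid) to the generator point
#' minimizing 3D Euclidean distance; a cell's area is the summed 3D area of
#' its triangles. Cells whose region touches the mesh boundary are the 3D
#' analogue of unbounded planar cells ("marginal") and are excluded from area
#' statistics.
#'
#' @param points 2-column `(x, y)` matrix / data frame (micrometres); lifted
#'   onto the mesh.
#' @param mesh a `surface_mesh`.
#' @return tibble with `id`, `x`, `y`, `finite`, `area_um2` and
#'   `metric = "euclidean3d"`. The areas of marginal cells are reported but
#'   flagged `finite = FALSE`.
#' @export
voronoi_3d <- function(points, mesh) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 1) stop("voronoi_3d needs at least one point")
  P3 <- lift_to_mesh(mesh, pts)
  cen <- tri_centroids_3d(mesh)
  assign <- nearest_node_cpp(cen, P3)
  a3 <- tri_areas_3d(mesh$vertices, mesh$triangles)
  btri <- boundary_triangles(mesh)
  area <- as.vector(tapply(a3, factor(assign, levels = seq_len(n)), sum))
  area[is.na(area)] <- 0
  marginal <- as.vector(tapply(btri, factor(assign, levels = seq_len(n)), any))
  marginal[is.na(marginal)] <- FALSE
  if (n == 1) marginal[1] <- TRUE  # whole mesh, necessarily touches boundary
  tibble::tibble(id = seq_len(n), x = pts[, 1], y = pts[, 2],
                 finite = !marginal, area_um2 = area, metric = "euclidean3d")
}
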