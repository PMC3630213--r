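# Elastic-map surface fitting.
#
# The leaf surface is modeled as an elastic map: a rectangular grid of 3D
# nodes joined by edges (stretching) and ribs (triples of consecutive nodes,
# bending), fitted to the height-map point cloud by EM. The node lattice is
# regular in (x, y) and only node heights move during fitting, so the fitted
# map is a single-valued height field z = f(x, y) — the form in which it is
# used downstream (bilinear evaluation, per-cell distortion).

#' Build the focus point cloud from a height map and a leaf mask
#'
#' One 3D point per retained in-mask pixel, scaled to micrometres.
#'
#' @param hm a `height_map`.
#' @param mask a `leaf_mask` (same pixel grid), or `NULL` to use all pixels.
#' @param cal a [calibration()]; defaults to the height map's.
#' @param subsample keep every `subsample`-th pixel in x and y (default 1).
#' @param weights optional H x W matrix of positive per-point weights.
#' @return a tibble with columns `x`, `y`, `z` (micrometres) and `w`.
#' @export
build_cloud <- function(hm, mask = NULL, cal = NULL, subsample = 1L,
                        weights = NULL) {
  stopifnot(inherits(hm, "height_map"))
  if (is.null(cal)) cal <- hm$calibration
  if (is.null(cal)) stop("a calibration is required to build the point cloud")
  H <- nrow(hm$z_index); W <- ncol(hm$z_index)
  m <- if (is.null(mask)) matrix(TRUE, H, W) else mask$mask
  if (!all(dim(m) == c(H, W))) stop("mask and height map shapes differ")
  subsample <- as.integer(subsample)
  if (subsample < 1L) stop("subsample must be >= 1")
  keep <- matrix(FALSE, H, W)
  keep[seq(1L, H, by = subsample), seq(1L, W, by = subsample)] <- TRUE
  sel <- which(m & keep)
  if (!length(sel)) stop("empty mask: no points to build the cloud from")
  row <- (sel - 1L) %% H          # 0-based y
  col <- (sel - 1L) %/% H         # 0-based x
  tibble::tibble(
    x = col * cal$um_per_px,
    y = row * cal$um_per_px,
    z = hm$z_index[sel] * cal$um_per_slice,
    w = if (is.null(weights)) 1 else weights[sel]
  )
}

#' Construct an elastic map directly
#'
#' Normally produced by [fit_elastic_map()]; direct construction is useful
#' for analytic test surfaces.
#'
#' @param z n x m matrix of node heights (micrometres); rows follow `node_y`,
#'   columns follow `node_x`.
#' @param node_x,node_y increasing lattice coordinates (micrometres) of the
#'   node columns (length m) and rows (length n).
#' @param lambda,mu stretching and bending coefficients (>= 0).
#' @return an `elastic_map` object.
#' @export
elastic_map <- function(z, node_x, node_y, lambda = 1e-4, mu = 1e-3) {
  z <- as.matrix(z)
  if (nrow(z) != length(node_y) || ncol(z) != length(node_x))
    stop("z must be length(node_y) x length(node_x)")
  if (lambda < 0 || mu < 0) stop("lambda and mu must be >= 0")
  structure(list(z = z, node_x = as.numeric(node_x), node_y = as.numeric(node_y),
                 grid_shape = c(length(node_y), length(node_x)),
                 lambda = lambda, mu = mu, energy_trace = NULL),
            class = "elastic_map")
}

#' Elastic map sampling an analytic surface z = f(x, y)
#' @param f vectorized function of (x, y) returning z (micrometres).
#' @param xlim,ylim domain limits (micrometres).
#' @param shape grid shape `(n, m)` (rows, columns).
#' @inheritParams elastic_map
#' @export
elastic_map_from_function <- function(f, xlim, ylim, shape = c(30L, 30L),
                                      lambda = 1e-4, mu = 1e-3) {
  node_x <- seq(xlim[1], xlim[2], length.out = shape[2])
  node_y <- seq(ylim[1], ylim[2], length.out = shape[1])
  z <- outer(node_y, node_x, function(y, x) f(x, y))
  elastic_map(z, node_x, node_y, lambda, mu)
}

#' @export
print.elastic_map <- function(x, ...) {
  cat(sprintf("<elastic_map> %d x %d nodes, lambda = %g, mu = %g\n",
              x$grid_shape[1], x$grid_shape[2], x$lambda, x$mu))
  if (!is.null(x$energy_trace))
    cat(sprintf("  fitted: %d EM iterations, final energy %.6g\n",
                length(x$energy_trace), x$energy_trace[length(x$energy_trace)]))
  invisible(x)
}

# Node positions as an N x 3 matrix, column-major over the (n, m) grid.
map_nodes <- function(map) {
  n <- map$grid_shape[1]; m <- map$grid_shape[2]
  cbind(x = rep(map$node_x, each = n),
        y = rep(map$node_y, times = m),
        z = as.vector(map$z))
}

# Edge index pairs and rib index triples of the (n, m) grid graph
# (|E| = n(m-1) + m(n-1); |R| = n*max(m-2,0) + m*max(n-2,0)).
grid_edges <- function(n, m) {
  id <- function(i, j) i + (j - 1L) * n
  i <- rep(seq_len(n), times = m - 1L); j <- rep(seq_len(m - 1L), each = n)
  horiz <- cbind(id(i, j), id(i, j + 1L))
  i <- rep(seq_len(n - 1L), times = m); j <- rep(seq_len(m), each = n - 1L)
  vert <- cbind(id(i, j), id(i + 1L, j))
  rbind(horiz, vert)
}

grid_ribs <- function(n, m) {
  id <- function(i, j) i + (j - 1L) * n
  out <- NULL
  if (m >= 3L) {
    i <- rep(seq_len(n), times = m - 2L); j <- rep(seq_len(m - 2L), each = n)
    out <- rbind(out, cbind(id(i, j), id(i, j + 1L), id(i, j + 2L)))
  }
  if (n >= 3L) {
    i <- rep(seq_len(n - 2L), times = m); j <- rep(seq_len(m), each = n - 2L)
    out <- rbind(out, cbind(id(i, j), id(i + 1L, j), id(i + 2L, j)))
  }
  if (is.null(out)) matrix(integer(0), 0, 3) else out
}

#' Elastic-map energy components
#'
#' `U_Y` is the weighted mean squared distance of the data points to their
#' host nodes (averaged over the number of points); `U_E = lambda * sum` of
#' squared edge lengths (stretching); `U_R = mu * sum` of squared second
#' differences along grid rows and columns (bending).
#'
#' @param map an `elastic_map`.
#' @param cloud tibble/data frame with `x`, `y`, `z` (and optional `w`), or
#'   `NULL` for no data term.
#' @param assignment integer vector mapping each point to its host node
#'   (column-major node index), or `NULL` to assign each point to its nearest
#'   node.
#' @return named list `U_Y`, `U_E`, `U_R`, `total`.
#' @export
elastic_energy <- function(map, cloud = NULL, assignment = NULL) {
  nodes <- map_nodes(map)
  n <- map$grid_shape[1]; m <- map$grid_shape[2]
  U_Y <- 0
  if (!is.null(cloud) && nrow(cloud) > 0) {
    P <- cbind(cloud$x, cloud$y, cloud$z)
    w <- if ("w" %in% names(cloud)) cloud$w else rep(1, nrow(P))
    if (is.null(assignment)) assignment <- nearest_node_cpp(P, nodes)
    if (any(assignment < 1L | assignment > nrow(nodes)))
      stop("assignment refers to nonexistent nodes")
    d2 <- rowSums((P - nodes[assignment, , drop = FALSE])^2)
    U_Y <- sum(w * d2) / nrow(P)
  }
  E <- grid_edges(n, m)
  U_E <- map$lambda * sum((nodes[E[, 1], ] - nodes[E[, 2], ])^2)
  R <- grid_ribs(n, m)
  U_R <- if (nrow(R)) {
    sec <- nodes[R[, 1], , drop = FALSE] - 2 * nodes[R[, 2], , drop = FALSE] +
      nodes[R[, 3], , drop = FALSE]
    map$mu * sum(sec^2)
  } else 0
  list(U_Y = U_Y, U_E = U_E, U_R = U_R, total = U_Y + U_E + U_R)
}

# Sparse z-step system matrix: diag(W)/|S| + lambda*L_E + mu*B'B, where the
# lattice spacing terms of U_E are constants in z and the lattice second
# differences of U_R vanish, so this minimizes the full 3D energy over z.
zstep_matrix <- function(n, m, node_w, n_pts, lambda, mu) {
  N <- n * m
  A <- Matrix::Diagonal(N, node_w / n_pts)
  if (lambda > 0) {
    E <- grid_edges(n, m)
    inc <- Matrix::sparseMatrix(
      i = rep(seq_len(nrow(E)), 2), j = as.vector(E),
      x = rep(c(1, -1), each = nrow(E)), dims = c(nrow(E), N))
    A <- A + lambda * Matrix::crossprod(inc)
  }
  R <- grid_ribs(n, m)
  if (mu > 0 && nrow(R)) {
    B <- Matrix::sparseMatrix(
      i = rep(seq_len(nrow(R)), 3), j = as.vector(R),
      x = rep(c(1, -2, 1), each = nrow(R)), dims = c(nrow(R), N))
    A <- A + mu * Matrix::crossprod(B)
  }
  A
}

#' Fit an elastic map to a point cloud by EM
#'
#' Alternates (E) assignment of every point to its nearest node in 3D and
#' (M) exact minimization of the total energy in the node heights given the
#' assignments (a sparse linear solve). The node lattice spans the cloud's
#' (x, y) bounding box; heights are initialized from the least-squares plane.
#' Coordinates are internally normalized by the largest bounding-box extent,
#' so `lambda` and `mu` act on a unit-scale problem regardless of leaf size.
#'
#' @param cloud tibble/data frame with columns `x`, `y`, `z` in micrometres
#'   (optional positive weights `w`).
#' @param grid_shape nodes `(n, m)` along y and x (default `c(30, 30)`).
#' @param lambda stretching coefficient (default 0.01).
#' @param mu bending coefficient (default 0.1).
#' @param max_iter maximum EM iterations (default 100).
#' @param tol relative total-energy decrease below which EM stops
#'   (default 1e-5).
#' @return a fitted `elastic_map` with an `energy_trace` attribute (total
#'   energy after every iteration, normalized coordinates).
#' @export
fit_elastic_map <- function(cloud, grid_shape = c(30L, 30L), lambda = 1e-4,
                            mu = 1e-3, max_iter = 100L, tol = 1e-5) {
  if (is.null(cloud) || nrow(cloud) == 0) stop("cloud must be non-empty")
  n <- as.integer(grid_shape[1]); m <- as.integer(grid_shape[2])
  if (n < 2L || m < 2L) stop("grid_shape entries must be >= 2")
  if (lambda < 0 || mu < 0) stop("lambda and mu must be >= 0")
  P0 <- cbind(cloud$x, cloud$y, cloud$z)
  w <- if ("w" %in% names(cloud)) cloud$w else rep(1, nrow(P0))
  if (any(w <= 0)) stop("weights must be positive")

  # normalize: shift to bbox origin, scale by largest lateral extent
  x0 <- min(P0[, 1]); y0 <- min(P0[, 2]); z0 <- min(P0[, 3])
  L <- max(max(P0[, 1]) - x0, max(P0[, 2]) - y0, 1e-12)
  P <- cbind((P0[, 1] - x0) / L, (P0[, 2] - y0) / L, (P0[, 3] - z0) / L)

  node_x <- seq(0, (max(P0[, 1]) - x0) / L, length.out = m)
  node_y <- seq(0, (max(P0[, 2]) - y0) / L, length.out = n)
  # least-squares plane initialization
  cf <- stats::lm.fit(cbind(1, P[, 1], P[, 2]), P[, 3])$coefficients
  cf[is.na(cf)] <- 0
  z <- outer(node_y, node_x, function(y, x) cf[1] + cf[2] * x + cf[3] * y)

  map <- elastic_map(z, node_x, node_y, lambda, mu)
  npts <- nrow(P)
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    nodes <- map_nodes(map)
    host <- nearest_node_cpp(P, nodes)
    node_w <- as.vector(tapply(w, factor(host, levels = seq_len(n * m)), sum))
    node_w[is.na(node_w)] <- 0
    if (lambda == 0 && mu == 0 && any(node_w == 0))
      stop("fit error: singular system, empty host nodes: ",
           paste(which(node_w == 0), collapse = ", "))
    A <- zstep_matrix(n, m, node_w, npts, lambda, mu)
    b <- as.vector(tapply(w * P[, 3], factor(host, levels = seq_len(n * m)), sum))
    b[is.na(b)] <- 0
    znew <- tryCatch(as.vector(Matrix::solve(A, b / npts)),
                     error = function(e)
                       stop("fit error: singular system (",
                            conditionMessage(e), "); empty host nodes: ",
                            paste(which(node_w == 0), collapse = ", ")))
    map$z <- matrix(znew, n, m)
    en <- elastic_energy(map, data.frame(x = P[, 1], y = P[, 2], z = P[, 3], w = w),
                         assignment = host)$total
    trace <- c(trace, en)
    if (is.finite(prev) && prev > 0 && (prev - en) / prev < tol) break
    prev <- en
  }
  # back to micrometres
  map$z <- map$z * L + z0
  map$node_x <- map$node_x * L + x0
  map$node_y <- map$node_y * L + y0
  map$energy_trace <- trace
  map
}

#' Evaluate the elastic-map surface at (x, y)
#'
#' Bilinear interpolation of node heights within the containing grid cell.
#'
#' @param map an `elastic_map`.
#' @param xy numeric vector `c(x, y)` or a 2-column matrix of query points
#'   (micrometres), inside the node lattice's bounding box.
#' @return z value(s) in micrometres.
#' @export
evaluate_surface <- function(map, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  xy <- as.matrix(xy)
  nx <- map$node_x; ny <- map$node_y
  eps <- 1e-9 * max(diff(range(nx)), diff(range(ny)))
  if (any(xy[, 1] < nx[1] - eps | xy[, 1] > nx[length(nx)] + eps |
          xy[, 2] < ny[1] - eps | xy[, 2] > ny[length(ny)] + eps))
    stop("domain error: query point outside the elastic map's bounding box")
  j <- pmin(pmax(findInterval(xy[, 1], nx), 1L), length(nx) - 1L)
  i <- pmin(pmax(findInterval(xy[, 2], ny), 1L), length(ny) - 1L)
  tx <- (xy[, 1] - nx[j]) / (nx[j + 1L] - nx[j])
  ty <- (xy[, 2] - ny[i]) / (ny[i + 1L] - ny[i])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  z <- map$z
  n <- nrow(z)
  v00 <- z[cbind(i, j)]; v01 <- z[cbind(i, j + 1L)]
  v10 <- z[cbind(i + 1L, j)]; v11 <- z[cbind(i + 1L, j + 1L)]
  out <- (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
  if (nrow(xy) == 1) out[[1]] else out
}

#' Triangulate an elastic map into a surface mesh
#'
#' Each grid cell is split into two triangles along the lower-left to
#' upper-right diagonal, giving `2(n-1)(m-1)` consistently oriented
#' triangles. An optional cell mask restricts the mesh to part of the grid.
#'
#' @param map an `elastic_map`.
#' @param cell_mask optional logical (n-1) x (m-1) matrix of grid cells to
#'   keep.
#' @return a `surface_mesh`: `vertices` (N x 3, micrometres), `triangles`
#'   (M x 3 vertex indices), `uv` (N x 2 lattice coordinates), and the grid.
#' @export
triangulate <- function(map, cell_mask = NULL) {
  n <- map$grid_shape[1]; m <- map$grid_shape[2]
  V <- map_nodes(map)
  id <- function(i, j) i + (j - 1L) * n
  i <- rep(seq_len(n - 1L), times = m - 1L)
  j <- rep(seq_len(m - 1L), each = n - 1L)
  keep <- if (is.null(cell_mask)) rep(TRUE, length(i)) else cell_mask[cbind(i, j)]
  i <- i[keep]; j <- j[keep]
  a <- id(i, j); b <- id(i, j + 1L); c <- id(i + 1L, j); d <- id(i + 1L, j + 1L)
  tris <- rbind(cbind(a, b, d), cbind(a, d, c))
  areas <- tri_areas_3d(V, tris)
  if (any(areas <= 0)) {
    bad <- which(areas <= 0)
    stop("mesh error: degenerate triangles in cells ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  structure(list(vertices = V, triangles = tris, uv = V[, 1:2],
                 grid = list(n = n, m = m, node_x = map$node_x,
                             node_y = map$node_y, cell_keep = keep)),
            class = "surface_mesh")
}

#' Construct a surface mesh directly
#'
#' Meshes normally come from [triangulate()]; direct construction supports
#' analytic fixtures (e.g. a latitude-longitude sphere parameterization).
#' Meshes without grid information support area, distortion and Voronoi
#' operations, but not (x, y) point location.
#'
#' @param vertices N x 3 matrix (micrometres).
#' @param triangles M x 3 integer matrix of 1-based vertex indices.
#' @param uv optional N x 2 matrix of lateral coordinates (defaults to the
#'   vertices' (x, y)).
#' @return a `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, uv = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), nrow(triangles), 3)
  if (ncol(vertices) != 3 || ncol(triangles) != 3)
    stop("vertices must be N x 3 and triangles M x 3")
  if (min(triangles) < 1 || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  areas <- tri_areas_3d(vertices, triangles)
  if (any(areas <= 0))
    stop("mesh error: degenerate triangles: ",
         paste(utils::head(which(areas <= 0), 10), collapse = ", "))
  structure(list(vertices = vertices, triangles = triangles,
                 uv = if (is.null(uv)) vertices[, 1:2] else as.matrix(uv),
                 grid = NULL),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

# 3D triangle areas for triangle index rows `tris` over vertex matrix V.
tri_areas_3d <- function(V, tris) {
  u <- V[tris[, 2], , drop = FALSE] - V[tris[, 1], , drop = FALSE]
  v <- V[tris[, 3], , drop = FALSE] - V[tris[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# Signed projected (x, y) triangle areas.
tri_areas_2d <- function(V, tris) {
  x1 <- V[tris[, 1], 1]; y1 <- V[tris[, 1], 2]
  x2 <- V[tris[, 2], 1]; y2 <- V[tris[, 2], 2]
  x3 <- V[tris[, 3], 1]; y3 <- V[tris[, 3], 2]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Serialize an elastic map to JSON / read it back
#' @param map an `elastic_map`.
#' @param path file path.
#' @export
write_elastic_map <- function(map, path) {
  jsonlite::write_json(
    list(grid_shape = map$grid_shape, node_x = map$node_x,
         node_y = map$node_y, z = map$z, lambda = map$lambda, mu = map$mu),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_elastic_map
#' @export
read_elastic_map <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  elastic_map(o$z, o$node_x, o$node_y, o$lambda, o$mu)
}

#' Export a surface mesh as ASCII PLY or OBJ (by file extension)
#' @param mesh a `surface_mesh`.
#' @param path output path ending in `.ply` or `.obj`.
#' @export
write_mesh <- function(mesh, path) {
  V <- mesh$vertices; Tm <- mesh$triangles
  if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    lines <- c(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
               sprintf("f %d %d %d", Tm[, 1], Tm[, 2], Tm[, 3]))
  } else {
    lines <- c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(Tm)),
               "property list uchar int vertex_indices", "end_header",
               sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
               sprintf("3 %d %d %d", Tm[, 1] - 1L, Tm[, 2] - 1L, Tm[, 3] - 1L))
  }
  writeLines(lines, path)
  invisible(path)
}
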