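# Independent oracles and fixture builders shared across tests. Everything
# here is deliberately written by a different route than the package code
# (double loops, finite differences, enumeration, pixel counting).

# Direct 3x3 convolution with edge replication (double loop).
conv3x3_oracle <- function(img, ker) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    acc <- 0
    for (u in -1:1) for (v in -1:1) {
      ii <- min(max(i + u, 1), H); jj <- min(max(j + v, 1), W)
      acc <- acc + ker[u + 2, v + 2] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Exhaustive Otsu scan: all candidate cuts of an n-bin histogram.
otsu_oracle <- function(v, n_bins = 256L) {
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  best <- -Inf; best_thr <- NA
  for (k in 1:(n_bins - 1)) {
    thr <- edges[k + 1]
    lo <- v[v <= thr]; hi <- v[v > thr]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    crit <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (crit > best + 1e-15) { best <- crit; best_thr <- thr }
  }
  best_thr
}

# Independent bilinear interpolation on a regular lattice.
bilinear_oracle <- function(z, xs, ys, qx, qy) {
  vapply(seq_along(qx), function(r) {
    j <- max(which(xs <= qx[r] + 1e-12)); j <- min(j, length(xs) - 1)
    i <- max(which(ys <= qy[r] + 1e-12)); i <- min(i, length(ys) - 1)
    tx <- (qx[r] - xs[j]) / (xs[j + 1] - xs[j])
    ty <- (qy[r] - ys[i]) / (ys[i + 1] - ys[i])
    (1 - ty) * ((1 - tx) * z[i, j] + tx * z[i, j + 1]) +
      ty * ((1 - tx) * z[i + 1, j] + tx * z[i + 1, j + 1])
  }, numeric(1))
}

# z-restricted elastic energy as a plain function of the node-height vector
# (for finite-difference quadratic solves and optim-based oracles).
zenergy_fn <- function(map, cloud, assignment) {
  force(map); force(cloud); force(assignment)
  function(zvec) {
    m2 <- map
    m2$z <- matrix(zvec, map$grid_shape[1], map$grid_shape[2])
    elastic_energy(m2, cloud, assignment)$total
  }
}

# Dense quadratic solve of the z-step by finite differences of the energy
# (exact for a quadratic): H z* = -g(0).
dense_zstep_oracle <- function(map, cloud, assignment) {
  f <- zenergy_fn(map, cloud, assignment)
  N <- prod(map$grid_shape)
  h <- 0.5   # central differences are exact for a quadratic; large h kills roundoff
  g0 <- vapply(seq_len(N), function(i) {
    e <- rep(0, N); e[i] <- h
    (f(e) - f(-e)) / (2 * h)
  }, numeric(1))
  H0 <- matrix(0, N, N)
  f00 <- f(rep(0, N))
  fi <- vapply(seq_len(N), function(i) { e <- rep(0, N); e[i] <- h; f(e) },
               numeric(1))
  for (i in seq_len(N)) for (j in i:N) {
    eij <- rep(0, N); eij[i] <- eij[i] + h; eij[j] <- eij[j] + h
    H0[i, j] <- H0[j, i] <- (f(eij) - fi[i] - fi[j] + f00) / h^2
  }
  solve(H0, -g0)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n_a + n_b, n_a) group assignments (Mann-Whitney U of sample a).
wilcoxon_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(ix) {
    ra <- rank(pooled)[ix]
    sum(ra) - na * (na + 1) / 2
  }
  obs <- u_of(seq_len(na))
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, u_of)
  p <- 2 * min(mean(us <= obs + 1e-12), mean(us >= obs - 1e-12))
  min(p, 1)
}

# Shoelace polygon area by explicit loop.
polygon_area_oracle <- function(poly) {
  n <- nrow(poly)
  acc <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    acc <- acc + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
  }
  abs(acc) / 2
}

# Pixel brute force: assign fine-grid pixel centers inside a polygon to the
# nearest generator; returns per-generator areas.
pixel_voronoi_oracle <- function(pts, poly, step) {
  xs <- seq(min(poly[, 1]) + step / 2, max(poly[, 1]), by = step)
  ys <- seq(min(poly[, 2]) + step / 2, max(poly[, 2]), by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- mgcv::in.out(rbind(poly, poly[1, ]), cbind(gx, gy))
  gx <- gx[inside]; gy <- gy[inside]
  d2 <- outer(gx, pts[, 1], "-")^2 + outer(gy, pts[, 2], "-")^2
  nearest <- max.col(-d2)
  counts <- tabulate(nearest, nbins = nrow(pts))
  counts * step^2
}

# Shared fixture builders -----------------------------------------------------

flat_mesh <- function(size = 100, n = 60L, z = 0) {
  triangulate(elastic_map_from_function(function(x, y) 0 * x + z,
                                        c(0, size), c(0, size), c(n, n)))
}

bumpy_map <- function(size = 200, n = 80L, amp = 40) {
  f <- function(x, y) amp * exp(-((x - size / 2)^2 + (y - size / 2)^2) /
                                  (2 * (size / 5)^2)) +
    0.25 * amp * sin(x / size * 4 * pi) * cos(y / size * 3 * pi)
  elastic_map_from_function(f, c(0, size), c(0, size), c(n, n))
}

hemisphere_cap_mesh <- function(r = 100, theta_max_deg = 75, n = 200L) {
  thmax <- theta_max_deg * pi / 180
  R <- r * sin(thmax)
  f <- function(x, y) sqrt(pmax(r^2 - pmin(x^2 + y^2, R^2), 0))
  m <- elastic_map_from_function(f, c(-R, R), c(-R, R), c(n, n))
  cx <- (m$node_x[-1] + m$node_x[-n]) / 2
  cy <- (m$node_y[-1] + m$node_y[-n]) / 2
  cm <- outer(cy, cx, function(y, x) x^2 + y^2 <= (0.999 * R)^2)
  triangulate(m, cell_mask = cm)
}

# Latitude-longitude hemisphere mesh (full cap to the equator).
hemisphere_latlong_mesh <- function(r = 100, n = 200L) {
  th <- seq(0, pi / 2, length.out = n)
  ph <- seq(0, 2 * pi, length.out = n)
  vx <- r * outer(sin(th), cos(ph))
  vy <- r * outer(sin(th), sin(ph))
  vz <- r * matrix(cos(th), n, n)
  V <- cbind(as.vector(vx), as.vector(vy), as.vector(vz))
  id <- function(i, j) i + (j - 1L) * n
  i <- rep(1:(n - 1), n - 1); j <- rep(1:(n - 1), each = n - 1)
  tris <- rbind(cbind(id(i, j), id(i, j + 1), id(i + 1, j + 1)),
                cbind(id(i, j), id(i + 1, j + 1), id(i + 1, j)))
  keep <- leafsurf:::tri_areas_3d(V, tris) > 1e-9
  surface_mesh(V, tris[keep, ])
}

# Tiny annotated leaf without any reconstruction.
toy_leaf <- function(genotype = "wt", leaf_id = "L1",
                     classes = c(1, 2, 3, 4, 4),
                     x_px = NULL, y_px = NULL, um_per_px = 2) {
  if (is.null(x_px)) x_px = 10 * seq_along(classes)
  if (is.null(y_px)) y_px = 10 * seq_along(classes) - 5
  tr <- tibble::tibble(trichome_id = seq_along(classes), class = classes,
                       x_px = x_px, y_px = y_px,
                       x_um = x_px * um_per_px, y_um = y_px * um_per_px)
  structure(list(trichomes = tr,
                 frame = leaf_frame(c(0, 0), c(0, 100)),
                 genotype = genotype, leaf_id = leaf_id,
                 um_per_px = um_per_px),
            class = "annotated_leaf")
}

# Random per-leaf statistics bundle (densities + morphometrics only), cheap
# enough for large null simulations.
random_leaf_stats <- function(genotype, n_leaves, density_shift = 0) {
  structure(list(
    density = tibble::tibble(
      leaf_id = rep(paste0(genotype, seq_len(n_leaves)), each = 4),
      genotype = genotype,
      class = rep(1:4, n_leaves),
      count = 5L,
      density_per_um2 = stats::rnorm(4 * n_leaves, 10 + density_shift, 1)),
    morpho = tibble::tibble(leaf_id = character(0), genotype = character(0),
                            area3d_um2 = numeric(0), length_um = numeric(0),
                            leaf_index = numeric(0)),
    trichome = tibble::tibble(leaf_id = character(0), genotype = character(0),
                              trichome_id = integer(0), class = integer(0),
                              voronoi2d_um2 = numeric(0),
                              voronoi3d_um2 = numeric(0),
                              nn_geodesic_um = numeric(0))
  ), class = "leaf_stats")
}
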