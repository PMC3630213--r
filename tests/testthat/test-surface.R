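fake_height_map <- function(z_index, um_per_px = 1, um_per_slice = 1) {
  structure(list(z_index = z_index,
                 z_um = z_index * um_per_slice,
                 textured = matrix(TRUE, nrow(z_index), ncol(z_index)),
                 calibration = calibration(um_per_px, um_per_slice),
                 n_slices = max(z_index) + 1L),
            class = "height_map")
}

test_that("point clouds are built from in-mask pixels in micrometres", {
  hm <- fake_height_map(matrix(0:3, 2, 2))
  cl <- build_cloud(hm, NULL)
  expect_equal(nrow(cl), 4L)
  expect_setequal(cl$z, 0:3)
  expect_equal(sort(unique(cl$x)), c(0, 1))

  hm4 <- fake_height_map(matrix(1L, 4, 4), um_per_px = 2, um_per_slice = 3.4)
  cl2 <- build_cloud(hm4, NULL, subsample = 2L)
  expect_equal(nrow(cl2), 4L)
  expect_setequal(cl2$x, c(0, 4))   # stride 2 px at 2 um/px
  expect_true(all(cl2$z == 3.4))

  empty <- leaf_mask(matrix(c(TRUE, rep(FALSE, 15)), 4, 4))
  empty$mask[] <- FALSE
  expect_error(build_cloud(hm4, empty), "empty mask")
})

test_that("edge and rib counts follow the grid formulas", {
  for (nm in list(c(2L, 2L), c(3L, 3L), c(1L, 3L), c(4L, 7L))) {
    n <- nm[1]; m <- nm[2]
    expect_equal(nrow(leafsurf:::grid_edges(n, m)), n * (m - 1) + m * (n - 1))
    expect_equal(nrow(leafsurf:::grid_ribs(n, m)),
                 n * max(m - 2, 0) + m * max(n - 2, 0))
  }
})

test_that("elastic energy components match hand evaluation", {
  # nodes exactly on the points, collinear equally spaced grid:
  # perfect fit and zero second difference
  m <- elastic_map(matrix(5, 1, 3), node_x = c(0, 1, 2), node_y = 0,
                   lambda = 0.5, mu = 1)
  cl <- tibble::tibble(x = c(0, 1, 2), y = 0, z = 5)
  en <- elastic_energy(m, cl, assignment = 1:3)
  expect_equal(en$U_Y, 0)
  expect_equal(en$U_R, 0)
  expect_equal(en$U_E, 0.5 * 2)  # two unit edges, squared length 1 each

  # 1D 3-node map, z = (0, 1, 0), unit spacing: rib second difference
  # (0,0,0) - 2*(x2,0,1) + (2,0,0) cancels in x, leaves (0-2+0)^2 = 4 in z
  m2 <- elastic_map(matrix(c(0, 1, 0), 1, 3), node_x = c(0, 1, 2), node_y = 0,
                    lambda = 0, mu = 1)
  expect_equal(elastic_energy(m2)$U_R, 4)
  expect_equal(elastic_energy(m2)$U_E, 0)  # lambda = 0

  # doubling all weights doubles U_Y, leaves U_E and U_R unchanged
  set.seed(21)
  m3 <- elastic_map(matrix(rnorm(9), 3, 3), node_x = 0:2, node_y = 0:2,
                    lambda = 0.3, mu = 0.7)
  cl3 <- tibble::tibble(x = runif(10, 0, 2), y = runif(10, 0, 2),
                        z = rnorm(10), w = runif(10, 0.5, 2))
  e1 <- elastic_energy(m3, cl3)
  cl3b <- cl3; cl3b$w <- 2 * cl3$w
  e2 <- elastic_energy(m3, cl3b)
  expect_equal(e2$U_Y, 2 * e1$U_Y)
  expect_equal(e2$U_E, e1$U_E)
  expect_equal(e2$U_R, e1$U_R)
})

test_that("one EM iteration on a 2x2 grid equals the dense quadratic oracle", {
  set.seed(22)
  cl <- tibble::tibble(x = c(0.1, 0.9, 0.12, 0.88),
                       y = c(0.1, 0.15, 0.9, 0.85),
                       z = c(0.3, 0.5, 0.2, 0.9))
  fit <- fit_elastic_map(cl, c(2L, 2L), lambda = 0.05, mu = 0, max_iter = 1L)
  # oracle in the fit's normalized coordinates: the documented E-step
  # (nearest node in 3D from the plane-fit initialization, here trivially one
  # point per corner) followed by a dense finite-difference solve of the
  # z-restricted quadratic program
  L <- max(diff(range(cl$x)), diff(range(cl$y)))
  cln <- tibble::tibble(x = (cl$x - min(cl$x)) / L, y = (cl$y - min(cl$y)) / L,
                        z = (cl$z - min(cl$z)) / L)
  nxr <- range(cln$x); nyr <- range(cln$y)
  cf <- stats::lm.fit(cbind(1, cln$x, cln$y), cln$z)$coefficients
  zinit <- outer(nyr, nxr, function(y, x) cf[1] + cf[2] * x + cf[3] * y)
  init_map <- elastic_map(zinit, nxr, nyr, lambda = 0.05, mu = 0)
  host <- leafsurf:::nearest_node_cpp(as.matrix(cln),
                                      leafsurf:::map_nodes(init_map))
  expect_equal(sort(host), 1:4)  # one point per corner node
  zstar <- dense_zstep_oracle(init_map, cln, host)
  fitted_norm <- (as.vector(fit$z) - min(cl$z)) / L
  expect_equal(fitted_norm, as.vector(zstar), tolerance = 1e-8)
})

test_that("EM fits a plane exactly and energy never increases", {
  # Node heights recover z = 2x + 3y exactly when the cloud samples the plane
  # at the node lattice (the host-node data term is a vector quantizer: with
  # area-sampled clouds, boundary nodes see one-sided host regions and pick up
  # an O(slope x spacing) offset; see the methods vignette).
  nx <- seq(0, 100, length.out = 12); ny <- seq(0, 80, length.out = 12)
  g <- expand.grid(y = ny, x = nx)
  cl <- tibble::tibble(x = g$x, y = g$y, z = 2 * g$x + 3 * g$y)
  m <- fit_elastic_map(cl, c(12L, 12L), lambda = 1e-12, mu = 1e-12, tol = 1e-12)
  plane <- outer(m$node_y, m$node_x, function(y, x) 2 * x + 3 * y)
  expect_lt(sqrt(mean((m$z - plane)^2)), 1e-6)
  # and the fitted surface evaluates to the plane everywhere
  set.seed(23)
  q <- cbind(runif(300, 0, 100), runif(300, 0, 80))
  expect_lt(max(abs(evaluate_surface(m, q) - (2 * q[, 1] + 3 * q[, 2]))), 1e-4)

  # monotone energy on random fixtures
  for (rep in 1:5) {
    cl2 <- tibble::tibble(x = runif(60), y = runif(60), z = rnorm(60))
    m2 <- fit_elastic_map(cl2, c(4L, 5L), lambda = 10^runif(1, -5, -1),
                          mu = 10^runif(1, -5, -1), max_iter = 25L, tol = 0)
    expect_true(all(diff(m2$energy_trace) <= 1e-10))
  }
})

test_that("unconstrained fit reaches the per-node centroid solution", {
  set.seed(24)
  # points clustered at the 4 corners of the unit square, 3x3 grid:
  # with lambda = mu -> 0 each hosting node converges to its cluster mean
  corners <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  cl <- tibble::tibble(
    x = rep(corners[, 1], each = 20) + runif(80, -0.03, 0.03),
    y = rep(corners[, 2], each = 20) + runif(80, -0.03, 0.03),
    z = rep(c(0, 1, 2, 3), each = 20) + rnorm(80, 0, 0.05))
  m <- fit_elastic_map(cl, c(3L, 3L), lambda = 1e-9, mu = 1e-9, max_iter = 50L)
  uy <- elastic_energy(m, cl)$U_Y
  # centroid oracle: assign to nearest node, replace node z by hosted mean
  nodes <- leafsurf:::map_nodes(m)
  host <- leafsurf:::nearest_node_cpp(as.matrix(cl[, c("x", "y", "z")]), nodes)
  zc <- tapply(cl$z, factor(host, levels = seq_len(nrow(nodes))), mean)
  lat <- nodes[, 1:2]
  d2 <- rowSums((as.matrix(cl[, c("x", "y")]) - lat[host, ])^2) +
    (cl$z - zc[host])^2
  expect_lte(uy, mean(d2) + 1e-6)
})

test_that("fitted bending energy decreases with the mu used for fitting", {
  set.seed(25)
  x <- runif(600, 0, 100); y <- runif(600, 0, 100)
  cl <- tibble::tibble(x = x, y = y, z = 0.3 * x + rnorm(600, 0, 4))
  ur <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2), function(mu) {
    m <- fit_elastic_map(cl, c(15L, 15L), lambda = 1e-5, mu = mu)
    m$mu <- 1
    elastic_energy(m)$U_R
  }, numeric(1))
  expect_true(all(diff(ur) <= 1e-9))
})

test_that("singular fits are reported with the empty nodes", {
  cl <- tibble::tibble(x = c(0, 1), y = c(0, 1), z = c(0, 1))
  expect_error(fit_elastic_map(cl, c(3L, 3L), lambda = 0, mu = 0),
               "empty host nodes")
})

test_that("surface evaluation is exact bilinear interpolation", {
  set.seed(26)
  nx <- seq(0, 10, length.out = 6); ny <- seq(0, 8, length.out = 5)
  z <- matrix(rnorm(30), 5, 6)
  m <- elastic_map(z, nx, ny)
  # at a node
  expect_equal(evaluate_surface(m, c(nx[3], ny[2])), z[2, 3])
  # cell center of a planar map equals the plane
  mp <- elastic_map(outer(ny, nx, function(y, x) 1 + 2 * x - y), nx, ny)
  expect_equal(evaluate_surface(mp, c(mean(nx[2:3]), mean(ny[3:4]))),
               1 + 2 * mean(nx[2:3]) - mean(ny[3:4]))
  # 1000 random queries against the independent bilinear oracle
  qx <- runif(1000, 0, 10); qy <- runif(1000, 0, 8)
  expect_lt(max(abs(evaluate_surface(m, cbind(qx, qy)) -
                      bilinear_oracle(z, nx, ny, qx, qy))), 1e-12)
  expect_error(evaluate_surface(m, c(-1, 4)), "domain error")
})

test_that("triangulation splits every cell along the same diagonal", {
  m <- elastic_map(matrix(0, 3, 3), node_x = 0:2, node_y = 0:2)
  mesh <- triangulate(m)
  expect_equal(nrow(mesh$triangles), 8L)
  expect_equal(nrow(mesh$vertices), 9L)

  # planar map: all normals parallel, 3D area equals the shoelace area of
  # the (x, y) bounding rectangle
  mp <- elastic_map_from_function(function(x, y) 2 + 0.5 * x - 0.25 * y,
                                  c(0, 4), c(0, 3), c(7L, 9L))
  meshp <- triangulate(mp)
  V <- meshp$vertices; Tm <- meshp$triangles
  normal <- function(t) {
    u <- V[Tm[t, 2], ] - V[Tm[t, 1], ]; v <- V[Tm[t, 3], ] - V[Tm[t, 1], ]
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    n / sqrt(sum(n^2))
  }
  n1 <- normal(1)
  expect_true(all(vapply(seq_len(nrow(Tm)), function(t)
    sum(abs(normal(t) - n1)) < 1e-12, logical(1))))
  # 3D area of the inclined plane = bbox area / cos(angle)
  slope <- sqrt(0.5^2 + 0.25^2)
  shoelace <- polygon_area_oracle(rbind(c(0, 0), c(4, 0), c(4, 3), c(0, 3)))
  expect_equal(area3d(meshp), shoelace * sqrt(1 + slope^2), tolerance = 1e-12)

  # degenerate cells (duplicate lattice coordinates) are refused
  bad <- elastic_map(matrix(0, 2, 3), node_x = c(0, 1, 1), node_y = 0:1)
  expect_error(triangulate(bad), "degenerate")
})

test_that("noisy smooth surfaces are recovered below the noise level", {
  set.seed(27)
  n <- 3000
  x <- runif(n, 0, 200); y <- runif(n, 0, 200)
  f <- function(x, y) 40 * exp(-((x - 100)^2 + (y - 100)^2) / (2 * 40^2))
  sigma <- 3
  cl <- tibble::tibble(x = x, y = y, z = f(x, y) + rnorm(n, 0, sigma))
  m <- fit_elastic_map(cl, c(30L, 30L))
  gx <- seq(10, 190, length.out = 35); gy <- seq(10, 190, length.out = 35)
  q <- as.matrix(expand.grid(gx, gy))
  rms <- sqrt(mean((evaluate_surface(m, q) - f(q[, 1], q[, 2]))^2))
  expect_lt(rms, sigma)
})

test_that("elastic maps serialize to JSON and back", {
  set.seed(28)
  m <- elastic_map(matrix(rnorm(12), 3, 4), node_x = c(0, 1, 3, 6),
                   node_y = c(0, 2, 5), lambda = 0.2, mu = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_elastic_map(m, path)
  m2 <- read_elastic_map(path)
  expect_equal(m2$z, m$z)
  expect_equal(m2$node_x, m$node_x)
  expect_equal(m2$lambda, m$lambda)
})
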