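test_that("2D and 3D Euclidean distances behave analytically", {
  expect_equal(dist2d(c(0, 0), c(3, 4)), 5)
  expect_equal(dist2d(c(2, 2), c(2, 2)), 0)
  set.seed(31)
  p <- matrix(runif(200), 100, 2); q <- matrix(runif(200), 100, 2)
  expect_equal(dist2d(p, q), dist2d(q, p))

  # flat map: dist3d equals dist2d
  mflat <- elastic_map_from_function(function(x, y) 0 * x + 7, c(0, 1), c(0, 1),
                                     c(5L, 5L))
  expect_equal(dist3d(c(0.1, 0.2), c(0.8, 0.9), mflat),
               dist2d(c(0.1, 0.2), c(0.8, 0.9)))
  # plane z = x: (0,0) to (1,0) has length sqrt(2)
  mx <- elastic_map_from_function(function(x, y) x, c(0, 1), c(0, 1), c(5L, 5L))
  expect_equal(dist3d(c(0, 0), c(1, 0), mx), sqrt(2))
  expect_error(dist3d(c(0, 0), c(2, 0), mx), "domain error")

  # dist3d >= dist2d on a bumpy fitted surface
  mb <- bumpy_map(size = 100, n = 40L, amp = 20)
  a <- cbind(runif(1000, 0, 100), runif(1000, 0, 100))
  b <- cbind(runif(1000, 0, 100), runif(1000, 0, 100))
  expect_true(all(dist3d(a, b, mb) >= dist2d(a, b) - 1e-12))
})

test_that("geodesics on a flat mesh reduce to planar distances", {
  mesh <- flat_mesh(size = 100, n = 100L)
  set.seed(32)
  for (k in 1:8) {
    a <- runif(2, 5, 95); b <- runif(2, 5, 95)
    expect_equal(geodesic_distance(mesh, a, b), dist2d(a, b),
                 tolerance = 5e-3)
  }
  expect_equal(geodesic_distance(mesh, c(40, 40), c(40, 40)), 0)
})

test_that("geodesic fields are symmetric and satisfy the triangle inequality", {
  mesh <- triangulate(bumpy_map(size = 100, n = 120L, amp = 25))
  set.seed(33)
  pts <- cbind(runif(6, 10, 90), runif(6, 10, 90))
  D <- matrix(0, 6, 6)
  for (i in 1:6) {
    f <- geodesic_field(mesh, pts[i, ])
    for (j in 1:6) if (j != i) D[i, j] <- leafsurf:::eval_field(mesh, f, pts[j, ], pts[i, ])
  }
  offdiag <- D[upper.tri(D)]
  rel <- abs(D - t(D)) / pmax(D, t(D), 1e-9)
  expect_lt(max(rel[upper.tri(rel)]), 0.01)
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    if (length(unique(c(i, j, k))) == 3)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 0.02 * D[i, j])
})

test_that("geodesic nearest neighbors match collinear logic and brute force", {
  mesh <- flat_mesh(size = 10, n = 100L)
  pts <- rbind(c(1, 5), c(3, 5), c(7, 5))  # x spacing 2, 2, 4
  nn <- geodesic_nn(mesh, pts)
  expect_equal(nn, c(2, 2, 4), tolerance = 5e-3)

  # symmetric pair
  nn2 <- geodesic_nn(mesh, rbind(c(3, 3), c(7, 7)))
  expect_equal(nn2[1], nn2[2], tolerance = 1e-9)

  # all-pairs brute force oracle on a bumpy mesh
  meshb <- triangulate(bumpy_map(size = 100, n = 40L, amp = 20))
  set.seed(34)
  p10 <- cbind(runif(10, 10, 90), runif(10, 10, 90))
  nn3 <- geodesic_nn(meshb, p10)
  oracle <- vapply(1:10, function(i) {
    min(vapply(setdiff(1:10, i), function(j)
      min(geodesic_distance(meshb, p10[i, ], p10[j, ]),
          geodesic_distance(meshb, p10[j, ], p10[i, ])), numeric(1)))
  }, numeric(1))
  expect_equal(nn3, oracle, tolerance = 1e-6)
  expect_error(geodesic_nn(meshb, p10[1, , drop = FALSE]), "at least 2")
})

test_that("2D areas: masks, polygons, Monte-Carlo oracle", {
  mk <- leaf_mask(rbind(matrix(TRUE, 10, 10), matrix(FALSE, 2, 10)))
  expect_equal(area2d(mk, um_per_px = 2), 100 * 4)
  expect_equal(area2d(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)

  set.seed(35)
  ang <- sort(runif(9, 0, 2 * pi))
  rad <- runif(9, 2, 5)
  poly <- cbind(5 + rad * cos(ang), 5 + rad * sin(ang))  # star-shaped, simple
  mc <- local({
    n <- 4e5
    px <- runif(n, 0, 10); py <- runif(n, 0, 10)
    mean(mgcv::in.out(rbind(poly, poly[1, ]), cbind(px, py))) * 100
  })
  expect_equal(area2d(poly), mc, tolerance = 0.01)
  expect_error(area2d(rbind(c(0, 0), c(1, 1), c(2, 2))), "empty region")
})

test_that("3D area dominates the projection and matches closed forms", {
  flat <- triangulate(elastic_map_from_function(function(x, y) 0 * x,
                                                c(0, 1), c(0, 1), c(12L, 12L)))
  expect_equal(area3d(flat), 1, tolerance = 1e-12)

  # plane inclined at 60 degrees: area = 2 x projected area
  inc <- triangulate(elastic_map_from_function(function(x, y) sqrt(3) * x,
                                               c(0, 50), c(0, 50), c(30L, 30L)))
  expect_equal(area3d(inc), 2 * 50 * 50, tolerance = 1e-9)

  # restriction to a region: half mask gives half the area
  m <- elastic_map_from_function(function(x, y) 0 * x, c(0, 9), c(0, 9),
                                 c(10L, 10L))
  mesh <- triangulate(m)
  half <- leaf_mask(cbind(matrix(TRUE, 10, 5), matrix(FALSE, 10, 5)))
  expect_equal(area3d(mesh, region = half, um_per_px = 1), 81 / 2,
               tolerance = 0.15)

  # bumpy surface: 3D area >= projected area
  mb <- triangulate(bumpy_map(size = 100, n = 40L, amp = 25))
  expect_gte(area3d(mb), 100 * 100)
})

test_that("distortion is cos(tilt) per triangle with a longitudinal profile", {
  flat <- flat_mesh(size = 10, n = 10L)
  dm <- distortion_map(flat)
  expect_true(all(abs(dm$triangles$ratio - 1) < 1e-12))

  inc <- triangulate(elastic_map_from_function(function(x, y) sqrt(3) * x,
                                               c(0, 50), c(0, 50), c(20L, 20L)))
  dmi <- distortion_map(inc, n_bins = 5)
  expect_true(all(abs(dmi$triangles$ratio - 0.5) < 1e-12))
  expect_true(all(abs(dmi$profile$mean - 0.5) < 1e-12))
  expect_true(all(dmi$profile$q25 <= dmi$profile$mean &
                    dmi$profile$mean <= dmi$profile$q75))

  mb <- triangulate(bumpy_map(size = 100, n = 30L, amp = 30))
  r <- distortion_map(mb)$triangles$ratio
  expect_true(all(r > 0 & r <= 1))
})

test_that("planar Voronoi cells: construction, clipping, oracle", {
  leafpoly <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))

  # 4 points at square corners: all hull points, no finite cell
  sq <- rbind(c(20, 20), c(80, 20), c(80, 80), c(20, 80))
  v <- voronoi_2d(sq, leafpoly)
  expect_true(all(!v$finite))

  # adding the center: its cell is half the square's area
  v5 <- voronoi_2d(rbind(sq, c(50, 50)), leafpoly)
  expect_equal(sum(v5$finite), 1L)
  expect_equal(v5$area_um2[5], 0.5 * 60^2)

  # random interior points: finite areas match the pixel oracle within 1%,
  # marginal set equals the convex hull generators
  set.seed(36)
  pts <- cbind(runif(12, 15, 85), runif(12, 15, 85))
  vr <- voronoi_2d(pts, leafpoly)
  hull <- sort(grDevices::chull(pts))
  expect_equal(sort(which(!vr$finite)), hull)
  orc <- pixel_voronoi_oracle(pts, leafpoly, step = 0.25)
  fin <- which(vr$finite)
  expect_equal(vr$area_um2[fin], orc[fin], tolerance = 0.01)
  # conservation: finite + excluded regions tile the leaf
  expect_lte(sum(vr$area_um2[fin]), area2d(leafpoly))
  expect_equal(sum(vr$area_um2[fin]) + sum(orc[!vr$finite]), area2d(leafpoly),
               tolerance = 0.01)

  expect_error(voronoi_2d(pts[1:2, ], leafpoly), "at least 3")
  expect_error(voronoi_2d(rbind(c(0, 0), c(1, 1), c(2, 2)), leafpoly),
               "collinear")
})

test_that("surface Voronoi by 3D distance matches the planar limit", {
  mesh <- flat_mesh(size = 100, n = 60L)
  set.seed(37)
  pts <- cbind(runif(9, 15, 85), runif(9, 15, 85))
  v3 <- voronoi_3d(pts, mesh)
  v2 <- voronoi_2d(pts, rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
  both <- which(v2$finite & v3$finite)
  expect_gt(length(both), 0)
  expect_equal(v3$area_um2[both], v2$area_um2[both], tolerance = 0.02)

  # symmetric pair about the midline: equal areas
  vp <- voronoi_3d(rbind(c(30, 50), c(70, 50)), mesh)
  expect_equal(vp$area_um2[1], vp$area_um2[2], tolerance = 1e-9)

  # single interior point owns the whole mesh but is marginal
  v1 <- voronoi_3d(matrix(c(50, 50), 1), mesh)
  expect_false(v1$finite[1])
  expect_equal(v1$area_um2[1], area3d(mesh))
  expect_error(voronoi_3d(matrix(numeric(0), 0, 2), mesh), "at least one")
})

test_that("the distance chain dist2d <= dist3d <= geodesic holds", {
  mp <- bumpy_map(size = 100, n = 50L, amp = 25)
  mesh <- triangulate(mp)
  set.seed(38)
  sources <- cbind(runif(5, 10, 90), runif(5, 10, 90))
  targets <- cbind(runif(40, 10, 90), runif(40, 10, 90))
  for (i in seq_len(nrow(sources))) {
    f <- geodesic_field(mesh, sources[i, ])
    for (j in seq_len(nrow(targets))) {
      a <- sources[i, ]; b <- targets[j, ]
      d2 <- dist2d(a, b)
      d3 <- dist3d(a, b, mp)
      dg <- leafsurf:::eval_field(mesh, f, b, a)
      expect_lte(d2, d3 + 1e-9)
      expect_lte(d3, dg + 0.01 * d3 + 1e-6)
    }
  }
})
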