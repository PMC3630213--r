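test_that("annotations load, validate and round-trip", {
  leaf <- toy_leaf()
  dir <- withr::local_tempdir()

  # CSV layout (trichome table + frame table)
  write_annotations(leaf, file.path(dir, "ann.csv"), file.path(dir, "frame.csv"))
  l2 <- load_annotations(file.path(dir, "ann.csv"), file.path(dir, "frame.csv"),
                         um_per_px = 2)
  expect_equal(nrow(l2$trichomes), 5L)
  expect_equal(l2$trichomes$x_um, leaf$trichomes$x_um)
  expect_equal(l2$frame$origin, leaf$frame$origin)
  expect_equal(l2$frame$tip, leaf$frame$tip)
  expect_equal(l2$genotype, "wt")

  # JSON layout
  write_annotations(leaf, file.path(dir, "ann.json"))
  l3 <- load_annotations(file.path(dir, "ann.json"), um_per_px = 2)
  expect_equal(l3$trichomes$class, leaf$trichomes$class)
  expect_equal(l3$frame$length_um, leaf$frame$length_um)

  # schema errors name the offending record / field
  bad <- leaf$trichomes[c("trichome_id", "x_px", "y_px", "class")]
  bad$class[2] <- 5
  expect_error(load_annotations(bad, leaf$frame), "invalid class 5")
  expect_error(load_annotations(bad, leaf$frame), "trichome_id=2")
  expect_error(load_annotations(bad[, -4], leaf$frame), "missing annotation fields")
  expect_error(load_annotations(bad, NULL), "no leaf frame")
})

test_that("the selection rule accepts 1-6 mature trichomes", {
  expect_false(select_leaf(toy_leaf(classes = c(1, 2, 3))))          # 0 mature
  expect_true(select_leaf(toy_leaf(classes = c(1, 4))))              # 1 mature
  expect_true(select_leaf(toy_leaf(classes = c(rep(4, 6), 1))))      # 6 mature
  expect_false(select_leaf(toy_leaf(classes = rep(4, 7))))           # 7 mature
})

test_that("frame normalization is a similarity transform", {
  fr <- leaf_frame(c(10, 20), c(10, 120))
  expect_equal(unlist(to_frame(c(10, 20), fr)), c(x = 0, y = 0))
  expect_equal(unlist(to_frame(c(10, 120), fr)), c(x = 0, y = 1))

  set.seed(41)
  pts <- cbind(runif(20, 0, 50), runif(20, 0, 80))
  base <- to_frame(pts, leaf_frame(c(5, 5), c(10, 70)))
  # rotate + translate + scale the pattern together with its frame
  th <- 0.7; s <- 2.3; tr <- c(31, -12)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts2 <- t(s * R %*% t(pts)) + rep(tr, each = 20)
  o2 <- s * as.vector(R %*% c(5, 5)) + tr
  t2 <- s * as.vector(R %*% c(10, 70)) + tr
  moved <- to_frame(pts2, leaf_frame(o2, t2))
  expect_equal(as.matrix(moved), as.matrix(base), tolerance = 1e-10)

  expect_error(leaf_frame(c(1, 1), c(1, 1)), "frame error")
})

test_that("meta leaves pool normalized records and conserve counts", {
  l1 <- toy_leaf(leaf_id = "L1")
  l2 <- toy_leaf(leaf_id = "L2", genotype = "cpc")
  meta <- build_metaleaf(list(l1, l2))
  expect_equal(nrow(meta), 10L)
  expect_equal(table(meta$class), table(c(l1$trichomes$class, l2$trichomes$class)))

  # duplicated leaf duplicates records exactly
  meta2 <- build_metaleaf(list(l1, l1))
  expect_equal(meta2$x[1:5], meta2$x[6:10])

  expect_error(build_metaleaf(list()), "at least one")
  expect_error(build_metaleaf(list(toy_leaf(classes = c(1, 2)))),
               "selection rule")
})

test_that("longitudinal profiles are per-bin class proportions", {
  # a pure class-1 metaleaf (built from a valid leaf, classes overwritten)
  meta <- build_metaleaf(list(toy_leaf()))
  meta$class <- 1L
  prof <- longitudinal_profile(meta, n_bins = 4)
  occ <- prof[prof$occupied & prof$class == 1, ]
  expect_true(all(occ$prop == 1))
  sums <- tapply(prof$prop[prof$occupied], prof$bin[prof$occupied], sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # hand-binned fixture: 10 records at known positions
  meta10 <- tibble::tibble(leaf_id = "L", genotype = "g",
                           class = c(1, 1, 2, 2, 3, 3, 4, 4, 1, 2),
                           x = 0, y = c(.05, .1, .3, .35, .55, .6, .8, .9, .07, .32))
  p <- longitudinal_profile(meta10, n_bins = 4)
  expect_equal(p$count[p$bin == 1 & p$class == 1], 3L)
  expect_equal(p$count[p$bin == 2 & p$class == 2], 3L)
  expect_equal(p$count[p$bin == 3 & p$class == 3], 2L)
  expect_equal(p$count[p$bin == 4 & p$class == 4], 2L)
  expect_equal(sum(p$count), 10L)
  expect_error(longitudinal_profile(meta10, n_bins = 0), ">= 1")
})

test_that("meta-leaf histograms conserve totals and match brute force", {
  set.seed(42)
  meta <- tibble::tibble(leaf_id = "L", genotype = "g",
                         class = sample(1:4, 50, TRUE),
                         x = runif(50, -0.5, 0.5), y = runif(50, 0, 1.2))
  h <- metaleaf_histogram(meta, grid = c(6L, 5L))
  expect_equal(sum(h$count), 50L)
  h1 <- metaleaf_histogram(meta, grid = c(1L, 1L))
  expect_equal(sum(h1$count), 50L)
  expect_equal(h1$count[order(h1$class)],
               as.integer(table(factor(meta$class, levels = 1:4)))[sort(unique(meta$class))])

  # brute-force bin check for one random cell
  bx <- seq(min(meta$x), max(meta$x), length.out = 7)
  by <- seq(min(meta$y), max(meta$y), length.out = 6)
  inside <- meta$x > bx[2] & meta$x <= bx[3] & meta$y > by[3] & meta$y <= by[4]
  want <- sum(inside & meta$class == 2)
  got <- h$count[h$ix == 2 & h$iy == 3 & h$class == 2]
  expect_equal(if (length(got)) got else 0L, want)
})

test_that("base distances are frame y coordinates in both unit systems", {
  leaf <- toy_leaf()
  bd <- base_distance(leaf)
  expect_equal(bd$y_norm, leaf$trichomes$y_um / 100)
  expect_equal(bd$y_um, leaf$trichomes$y_um)
  # trichome exactly on the baseline and at the tip
  l2 <- toy_leaf(classes = c(1, 4), x_px = c(0, 0), y_px = c(0, 50))
  bd2 <- base_distance(l2)
  expect_equal(bd2$y_norm, c(0, 1))

  # ordering preserved under a similarity transform of leaf + frame
  set.seed(43)
  th <- 1.1; s <- 0.6; tr <- c(-4, 9)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  l3 <- toy_leaf()
  pts2 <- t(s * R %*% t(cbind(l3$trichomes$x_um, l3$trichomes$y_um))) +
    rep(tr, each = 5)
  l3$trichomes$x_um <- pts2[, 1]; l3$trichomes$y_um <- pts2[, 2]
  l3$frame <- leaf_frame(s * as.vector(R %*% c(0, 0)) + tr,
                         s * as.vector(R %*% c(0, 100)) + tr)
  expect_equal(base_distance(l3)$y_norm, bd$y_norm, tolerance = 1e-10)
})

test_that("densities are counts per 3D area and additive across classes", {
  leaf <- toy_leaf(classes = c(1, 2, 3, 4))
  d <- trichome_density(leaf, 400)
  expect_equal(d$density_per_um2[is.na(d$class)], 4 / 400)
  expect_equal(d$density_per_um2[!is.na(d$class)], rep(1 / 400, 4))
  expect_equal(sum(d$density_per_um2[!is.na(d$class)]),
               d$density_per_um2[is.na(d$class)])
  d2 <- trichome_density(leaf, 800)
  expect_equal(d2$density_per_um2, d$density_per_um2 / 2)
  expect_error(trichome_density(leaf, 0), "positive")
})

test_that("class abundance averages per-leaf percentages", {
  l <- toy_leaf(classes = c(1, 2, 3, 4, 4))
  ab <- class_abundance(list(l, l, l))
  expect_equal(ab$sd_pct, rep(0, 4))
  expect_equal(sum(ab$mean_pct), 100)
  expect_equal(ab$mean_pct[ab$class == 4], 40)

  l2 <- toy_leaf(classes = c(1, 1, 1, 4))
  ab2 <- class_abundance(list(l, l2))
  expect_equal(ab2$mean_pct[ab2$class == 1], mean(c(20, 75)))
  expect_equal(ab2$n_leaves, rep(2L, 4))
})

test_that("leaf morphometrics: length along the axis and moment leaf index", {
  # circular mask: leaf index ~ 1
  H <- 101
  circ <- leaf_mask(outer(1:H, 1:H, function(i, j)
    (i - 51)^2 + (j - 51)^2 <= 40^2))
  fr <- leaf_frame(c(50, 10), c(50, 90))
  mo <- leaf_morphometrics(circ, fr, um_per_px = 1)
  expect_equal(mo$leaf_index, 1, tolerance = 0.02)

  # 2:1 ellipse: leaf index ~ 0.5, invariant under rotation
  ell <- leaf_mask(outer(1:121, 1:121, function(i, j)
    ((i - 61) / 50)^2 + ((j - 61) / 25)^2 <= 1))
  mo2 <- leaf_morphometrics(ell, leaf_frame(c(60, 10), c(60, 110)))
  expect_equal(mo2$leaf_index, 0.5, tolerance = 0.02)
  ell_rot <- leaf_mask(outer(1:121, 1:121, function(i, j) {
    u <- (i - 61) * cos(0.6) + (j - 61) * sin(0.6)
    v <- -(i - 61) * sin(0.6) + (j - 61) * cos(0.6)
    (u / 50)^2 + (v / 25)^2 <= 1
  }))
  mo3 <- leaf_morphometrics(ell_rot, leaf_frame(c(60, 10), c(60, 110)))
  expect_equal(mo3$leaf_index, mo2$leaf_index, tolerance = 0.02)

  # length: distance from origin to the mask top along the axis
  expect_equal(mo2$length_um, 110 - 10, tolerance = 1)
  empty <- circ; empty$mask[] <- FALSE; empty$mask[1, 1] <- TRUE
  expect_error(leaf_morphometrics(empty, fr), "degenerate")
})

test_that("rank-sum tests switch between exact and approximate correctly", {
  w <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_equal(w$method, "exact")

  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # exact p equals full enumeration for random small samples
  set.seed(44)
  for (na in c(2, 4, 6)) for (nb in c(3, 5)) {
    a <- rnorm(na); b <- rnorm(nb, 0.5)
    expect_equal(wilcoxon_ranksum(a, b)$p_value, wilcoxon_enum_oracle(a, b),
                 tolerance = 1e-12)
  }

  # large / tied samples use the normal approximation
  set.seed(45)
  w2 <- wilcoxon_ranksum(rnorm(15), rnorm(15))
  expect_equal(w2$method, "normal approximation")
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("genotype comparisons flag mature-trichome rows and self-compare to p = 1", {
  set.seed(46)
  a <- random_leaf_stats("wt", 8)
  cmp <- compare_genotypes(a, a)
  tb <- tidy(cmp)
  tested <- tb[tb$tested, ]
  expect_true(all(tested$p_value == 1))
  expect_false(tb$tested[tb$statistic == "density" & tb$class == 4])
  expect_match(tb$note[tb$statistic == "density" & tb$class == 4], "mature")
  expect_s3_class(glance(cmp), "tbl_df")

  empty <- random_leaf_stats("x", 1)
  empty$density <- empty$density[0, ]
  expect_error(compare_genotypes(empty, a), "both groups")
})
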