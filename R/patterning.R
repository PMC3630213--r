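# Trichome annotations, the leaf coordinate frame, meta-leaf pooling,
# class-stratified statistics and the two-genotype comparison.
#
# Trichome developmental classes: 1 = initiation (unbranched), 2 = two
# branches, 3 = three branches, 4 = mature (incrusted cell wall).

TRICHOME_CLASSES <- 1:4

#' Leaf coordinate frame
#'
#' The origin sits in the middle of the petiole at the base of the leaf
#' lamina; the longitudinal (y) axis points from the origin to `tip` and has
#' unit length after normalization, which implicitly fixes the direction and
#' scale of the perpendicular baseline x axis.
#'
#' @param origin,tip `(x, y)` points in micrometres; must differ.
#' @return a `leaf_frame`.
#' @export
leaf_frame <- function(origin, tip) {
  origin <- as.numeric(origin); tip <- as.numeric(tip)
  len <- sqrt(sum((tip - origin)^2))
  if (!is.finite(len) || len <= 0)
    stop("frame error: origin and tip must be distinct finite points")
  structure(list(origin = origin, tip = tip, length_um = len),
            class = "leaf_frame")
}

#' @export
print.leaf_frame <- function(x, ...) {
  cat(sprintf("<leaf_frame> origin (%.4g, %.4g), tip (%.4g, %.4g), axis %.4g um\n",
              x$origin[1], x$origin[2], x$tip[1], x$tip[2], x$length_um))
  invisible(x)
}

#' Centroid-based frame suggestion
#'
#' An alternative frame definition: the longitudinal axis points
#' from a user-chosen origin towards the leaf's center of mass.
#'
#' @param mask a `leaf_mask`.
#' @param origin `(x, y)` origin in micrometres (base of the lamina).
#' @param um_per_px lateral scale.
#' @return a `leaf_frame` whose tip is the mask centroid.
#' @export
suggest_frame <- function(mask, origin, um_per_px = 1) {
  idx <- which(mask$mask)
  H <- nrow(mask$mask)
  cx <- mean((idx - 1L) %/% H) * um_per_px
  cy <- mean((idx - 1L) %% H) * um_per_px
  leaf_frame(origin, c(cx, cy))
}

#' Transform (x, y) positions into normalized leaf-frame coordinates
#'
#' Translates by -origin, rotates the longitudinal axis onto +y and scales by
#' the axis length, so the axis tip maps to (0, 1). The transform is a
#' similarity: patterns rigidly moved/rotated/scaled together with their
#' frame give identical normalized coordinates.
#'
#' @param xy `(x, y)` vector, 2-column matrix, or data frame with `x_um`,
#'   `y_um` columns (micrometres).
#' @param frame a `leaf_frame`.
#' @return tibble with normalized `x`, `y`.
#' @export
to_frame <- function(xy, frame) {
  if (is.data.frame(xy)) xy <- cbind(xy$x_um, xy$y_um)
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  ax <- (frame$tip - frame$origin) / frame$length_um
  perp <- c(ax[2], -ax[1])
  dx <- xy[, 1] - frame$origin[1]
  dy <- xy[, 2] - frame$origin[2]
  tibble::tibble(
    x = (dx * perp[1] + dy * perp[2]) / frame$length_um,
    y = (dx * ax[1] + dy * ax[2]) / frame$length_um
  )
}

#' Read trichome annotations (positions + developmental class + frame)
#'
#' Two plain-text layouts are supported. CSV: a trichome table with columns
#' `leaf_id, genotype, trichome_id, x_px, y_px, class`, plus a frame table
#' (`frame` argument) with `origin_x_px, origin_y_px, tip_x_px, tip_y_px`.
#' JSON: one object per leaf with fields `leaf_id`, `genotype`, `frame`
#' (named list) and `trichomes` (records). Positions are converted to
#' micrometres with `um_per_px`.
#'
#' @param path annotation CSV or JSON path (or a data frame).
#' @param frame frame CSV path / data frame / `leaf_frame` (CSV layout only).
#' @param um_per_px lateral scale (micrometres per pixel).
#' @return an `annotated_leaf`: list with `trichomes` tibble (`trichome_id`,
#'   `class`, `x_px`, `y_px`, `x_um`, `y_um`), `frame`, `genotype`, `leaf_id`.
#' @export
load_annotations <- function(path, frame = NULL, um_per_px = 1) {
  if (is.character(path) && grepl("\\.json$", path, ignore.case = TRUE)) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    tr <- tibble::as_tibble(o$trichomes)
    fr <- leaf_frame(c(o$frame$origin_x_px, o$frame$origin_y_px) * um_per_px,
                     c(o$frame$tip_x_px, o$frame$tip_y_px) * um_per_px)
    genotype <- o$genotype; leaf_id <- o$leaf_id
  } else {
    tr <- if (is.character(path)) {
      tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    } else tibble::as_tibble(path)
    if (is.null(frame)) stop("schema error: no leaf frame supplied")
    fr <- if (inherits(frame, "leaf_frame")) frame else {
      fdf <- if (is.character(frame)) utils::read.csv(frame) else frame
      leaf_frame(c(fdf$origin_x_px[1], fdf$origin_y_px[1]) * um_per_px,
                 c(fdf$tip_x_px[1], fdf$tip_y_px[1]) * um_per_px)
    }
    genotype <- if ("genotype" %in% names(tr)) tr$genotype[1] else NA_character_
    leaf_id <- if ("leaf_id" %in% names(tr)) tr$leaf_id[1] else NA
  }
  need <- c("trichome_id", "x_px", "y_px", "class")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("schema error: missing annotation fields: ", paste(miss, collapse = ", "))
  bad <- which(!(tr$class %in% TRICHOME_CLASSES))
  if (length(bad))
    stop("schema error: invalid class ", tr$class[bad[1]],
         " in record trichome_id=", tr$trichome_id[bad[1]],
         " (classes must be 1-4)")
  tr$x_um <- tr$x_px * um_per_px
  tr$y_um <- tr$y_px * um_per_px
  structure(list(trichomes = tr[c("trichome_id", "class", "x_px", "y_px",
                                  "x_um", "y_um")],
                 frame = fr, genotype = genotype, leaf_id = leaf_id,
                 um_per_px = um_per_px),
            class = "annotated_leaf")
}

#' Write an annotated leaf back to CSV (trichomes + frame) or JSON
#' @param leaf an `annotated_leaf`.
#' @param path annotation CSV (or JSON) path.
#' @param frame_path frame CSV path (CSV layout only).
#' @export
write_annotations <- function(leaf, path, frame_path = NULL) {
  upp <- leaf$um_per_px
  fr <- data.frame(origin_x_px = leaf$frame$origin[1] / upp,
                   origin_y_px = leaf$frame$origin[2] / upp,
                   tip_x_px = leaf$frame$tip[1] / upp,
                   tip_y_px = leaf$frame$tip[2] / upp)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(leaf_id = leaf$leaf_id, genotype = leaf$genotype,
           frame = as.list(fr),
           trichomes = leaf$trichomes[c("trichome_id", "class", "x_px", "y_px")]),
      path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- data.frame(leaf_id = leaf$leaf_id, genotype = leaf$genotype,
                     leaf$trichomes[c("trichome_id", "x_px", "y_px", "class")])
    utils::write.csv(df, path, row.names = FALSE)
    if (!is.null(frame_path)) utils::write.csv(fr, frame_path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.annotated_leaf <- function(x, ...) {
  cat(sprintf("<annotated_leaf> %s (%s): %d trichomes, classes %s\n",
              x$leaf_id, x$genotype, nrow(x$trichomes),
              paste(sort(unique(x$trichomes$class)), collapse = ",")))
  invisible(x)
}

#' Leaf selection rule: one to six mature trichomes
#'
#' Leaves are comparable only at matched developmental stage; a leaf is
#' accepted iff it carries between 1 and 6 mature (class 4) trichomes.
#'
#' @param x an `annotated_leaf` or a trichome tibble with a `class` column.
#' @return logical accept flag.
#' @export
select_leaf <- function(x) {
  cls <- if (inherits(x, "annotated_leaf")) x$trichomes$class else x$class
  n4 <- sum(cls == 4L)
  n4 >= 1L && n4 <= 6L
}

#' Pool frame-normalized trichome positions across leaves into a meta leaf
#'
#' @param leaves list of `annotated_leaf` objects, all passing [select_leaf()].
#' @return a `metaleaf` tibble: `leaf_id`, `genotype`, `class`, `x`, `y`
#'   (normalized frame coordinates; the axis tip is at y = 1).
#' @export
build_metaleaf <- function(leaves) {
  if (inherits(leaves, "annotated_leaf")) leaves <- list(leaves)
  if (!length(leaves)) stop("build_metaleaf needs at least one leaf")
  rejected <- which(!vapply(leaves, select_leaf, logical(1)))
  if (length(rejected))
    stop("leaves failing the mature-trichome selection rule: ",
         paste(rejected, collapse = ", "))
  recs <- purrr::map_dfr(leaves, function(l) {
    nc <- to_frame(l$trichomes, l$frame)
    tibble::tibble(leaf_id = l$leaf_id, genotype = l$genotype,
                   class = l$trichomes$class, x = nc$x, y = nc$y)
  })
  class(recs) <- c("metaleaf", class(recs))
  recs
}

#' Class proportions along the longitudinal axis of the meta leaf
#'
#' @param meta a `metaleaf` tibble.
#' @param n_bins number of bins over normalized y in `[0, max(y)]`.
#' @return tibble `bin`, `y_mid`, `class`, `count`, `prop`, `occupied`;
#'   proportions sum to 1 in occupied bins.
#' @export
longitudinal_profile <- function(meta, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  brk <- seq(0, max(meta$y), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(meta$y, brk, rightmost.closed = TRUE), 1L), n_bins)
  grid <- tidyr::expand_grid(bin = seq_len(n_bins), class = TRICHOME_CLASSES)
  counts <- dplyr::count(tibble::tibble(bin = bin, class = meta$class),
                         .data$bin, .data$class, name = "count")
  out <- dplyr::left_join(grid, counts, by = c("bin", "class"))
  out$count[is.na(out$count)] <- 0L
  out <- dplyr::mutate(dplyr::group_by(out, .data$bin),
                       total = sum(.data$count),
                       prop = ifelse(.data$total > 0, .data$count / .data$total, NA_real_),
                       occupied = .data$total > 0)
  out <- dplyr::ungroup(out)
  out$y_mid <- (brk[out$bin] + brk[out$bin + 1L]) / 2
  out[c("bin", "y_mid", "class", "count", "prop", "occupied")]
}

#' 2D histogram of trichome classes on the meta leaf
#' @param meta a `metaleaf` tibble.
#' @param grid `(nx, ny)` cell counts over the meta leaf's bounding box.
#' @return tibble `ix`, `iy`, `x_mid`, `y_mid`, `class`, `count`; total count
#'   equals the number of records.
#' @export
metaleaf_histogram <- function(meta, grid = c(10L, 10L)) {
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  bx <- seq(min(meta$x), max(meta$x), length.out = nx + 1L)
  by <- seq(min(meta$y), max(meta$y), length.out = ny + 1L)
  ix <- pmin(pmax(findInterval(meta$x, bx, rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(meta$y, by, rightmost.closed = TRUE), 1L), ny)
  out <- dplyr::count(tibble::tibble(ix = ix, iy = iy, class = meta$class),
                      .data$ix, .data$iy, .data$class, name = "count")
  out$x_mid <- (bx[out$ix] + bx[out$ix + 1L]) / 2
  out$y_mid <- (by[out$iy] + by[out$iy + 1L]) / 2
  out[c("ix", "iy", "x_mid", "y_mid", "class", "count")]
}

#' Trichome distances from the leaf base line
#'
#' The signed distance of each trichome from the baseline x axis, i.e. its
#' frame y coordinate, in both normalized units (axis tip = 1) and
#' micrometres.
#'
#' @param leaf an `annotated_leaf`.
#' @return tibble `trichome_id`, `class`, `y_norm`, `y_um`.
#' @export
base_distance <- function(leaf) {
  nc <- to_frame(leaf$trichomes, leaf$frame)
  tibble::tibble(trichome_id = leaf$trichomes$trichome_id,
                 class = leaf$trichomes$class,
                 y_norm = nc$y, y_um = nc$y * leaf$frame$length_um)
}

#' Per-class trichome density on the 3D leaf surface
#'
#' Counts per square micrometre of 3D leaf area (elastic-map surface area).
#'
#' @param leaf an `annotated_leaf` (or trichome tibble with `class`).
#' @param area_um2 3D leaf area, e.g. `area3d(mesh, mask, um_per_px)`.
#' @return tibble `class` (1-4 and `NA` row for all classes pooled),
#'   `count`, `density_per_um2`.
#' @export
trichome_density <- function(leaf, area_um2) {
  if (!is.finite(area_um2) || area_um2 <= 0) stop("leaf area must be positive")
  cls <- if (inherits(leaf, "annotated_leaf")) leaf$trichomes$class else leaf$class
  counts <- vapply(TRICHOME_CLASSES, function(k) sum(cls == k), integer(1))
  tibble::tibble(class = c(TRICHOME_CLASSES, NA),
                 count = c(counts, length(cls)),
                 density_per_um2 = .data$count / area_um2)
}

#' Relative abundance of trichome classes per genotype
#'
#' Per-leaf class proportions (percent), averaged within genotype with the
#' across-leaf standard deviation.
#'
#' @param leaves list of `annotated_leaf` objects.
#' @return tibble `genotype`, `class`, `mean_pct`, `sd_pct`, `n_leaves`.
#' @export
class_abundance <- function(leaves) {
  per_leaf <- purrr::map_dfr(leaves, function(l) {
    cls <- l$trichomes$class
    tibble::tibble(genotype = l$genotype, leaf_id = l$leaf_id,
                   class = TRICHOME_CLASSES,
                   pct = vapply(TRICHOME_CLASSES,
                                function(k) 100 * sum(cls == k) / length(cls),
                                numeric(1)))
  })
  dplyr::summarise(dplyr::group_by(per_leaf, .data$genotype, .data$class),
                   mean_pct = mean(.data$pct),
                   sd_pct = stats::sd(.data$pct),
                   n_leaves = dplyr::n(), .groups = "drop")
}

#' Leaf morphometrics: 3D area, length, leaf index
#'
#' Length is the distance from the frame origin to the leaf top measured
#' along the longitudinal axis; the leaf index is the minor/major axis ratio
#' of the mask's best-fit ellipse (second image moments), in `(0, 1]`.
#'
#' @param mask a `leaf_mask`.
#' @param frame a `leaf_frame`.
#' @param mesh a `surface_mesh` (for the 3D area), or `NULL`.
#' @param um_per_px lateral scale.
#' @return tibble `area3d_um2`, `length_um`, `leaf_index`.
#' @export
leaf_morphometrics <- function(mask, frame, mesh = NULL, um_per_px = 1) {
  idx <- which(mask$mask)
  if (length(idx) < 3) stop("degenerate mask")
  H <- nrow(mask$mask)
  x <- ((idx - 1L) %/% H) * um_per_px
  y <- ((idx - 1L) %% H) * um_per_px
  ax <- (frame$tip - frame$origin) / frame$length_um
  proj <- (x - frame$origin[1]) * ax[1] + (y - frame$origin[2]) * ax[2]
  len <- max(proj)
  cx <- x - mean(x); cy <- y - mean(y)
  cov <- matrix(c(mean(cx^2), mean(cx * cy), mean(cx * cy), mean(cy^2)), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)$values
  if (ev[1] <= 0) stop("degenerate mask")
  li <- sqrt(max(ev[2], 0) / ev[1])
  tibble::tibble(
    area3d_um2 = if (is.null(mesh)) NA_real_ else
      area3d(mesh, region = mask, um_per_px = um_per_px),
    length_um = len,
    leaf_index = li
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when `n_a + n_b <= 20` and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param a,b numeric samples (non-empty).
#' @return list `statistic` (Mann-Whitney W of `a`), `p_value`, `method`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
       method = if (exact) "exact" else "normal approximation")
}

# ---- per-leaf statistics and genotype comparison ----------------------------

#' Spatial statistics of one reconstructed, annotated leaf
#'
#' Computes everything the genotype comparison consumes: per-class density
#' (on the 3D area), per-trichome 2D/3D Voronoi areas and geodesic
#' nearest-neighbor distance, and leaf morphometrics.
#'
#' @param leaf an `annotated_leaf`.
#' @param mesh the leaf's `surface_mesh`.
#' @param mask the `leaf_mask`.
#' @param um_per_px lateral scale.
#' @return `leaf_stats` object: tibbles `density`, `morpho`, `trichome`.
#' @export
leaf_statistics <- function(leaf, mesh, mask, um_per_px = 1) {
  tr <- leaf$trichomes
  pts <- cbind(tr$x_um, tr$y_um)
  a3 <- area3d(mesh, region = mask, um_per_px = um_per_px)
  dens <- trichome_density(leaf, a3)
  dens <- tibble::tibble(leaf_id = leaf$leaf_id, genotype = leaf$genotype,
                         dens[!is.na(dens$class), ])
  morpho <- tibble::tibble(leaf_id = leaf$leaf_id, genotype = leaf$genotype,
                           leaf_morphometrics(mask, leaf$frame, mesh, um_per_px))
  v2 <- if (nrow(tr) >= 3) voronoi_2d(pts, mask, um_per_px) else NULL
  v3 <- if (nrow(tr) >= 2) voronoi_3d(pts, mesh) else NULL
  nn <- if (nrow(tr) >= 2) geodesic_nn(mesh, pts) else rep(NA_real_, nrow(tr))
  trich <- tibble::tibble(
    leaf_id = leaf$leaf_id, genotype = leaf$genotype,
    trichome_id = tr$trichome_id, class = tr$class,
    voronoi2d_um2 = if (is.null(v2)) NA_real_ else
      ifelse(v2$finite, v2$area_um2, NA_real_),
    voronoi3d_um2 = if (is.null(v3)) NA_real_ else
      ifelse(v3$finite, v3$area_um2, NA_real_),
    nn_geodesic_um = nn
  )
  structure(list(density = dens, morpho = morpho, trichome = trich),
            class = "leaf_stats")
}

#' Combine per-leaf statistics into one group object
#' @param stats list of `leaf_stats` (or a single one).
#' @return a `leaf_stats` with rows pooled across leaves.
#' @export
combine_leaf_stats <- function(stats) {
  if (inherits(stats, "leaf_stats")) return(stats)
  structure(list(
    density = purrr::map_dfr(stats, "density"),
    morpho = purrr::map_dfr(stats, "morpho"),
    trichome = purrr::map_dfr(stats, "trichome")
  ), class = "leaf_stats")
}

#' Compare trichome patterning statistics between two genotypes
#'
#' Wilcoxon rank-sum tests per statistic: per-class density, leaf area,
#' length and leaf index across leaves; per-class 2D/3D Voronoi areas and the
#' geodesic nearest-neighbor distance across trichomes. Because leaves are
#' selected by their mature-trichome count, class-4 (mature) comparisons are
#' reported but flagged not tested. P-values are raw (as in the source
#' analysis); a Benjamini-Hochberg column is added for reference.
#'
#' @param stats_a,stats_b `leaf_stats` objects (or lists of them) for the two
#'   genotypes.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return a `genotype_comparison`; see [tidy.genotype_comparison()].
#' @export
compare_genotypes <- function(stats_a, stats_b, alpha = 0.05) {
  A <- combine_leaf_stats(stats_a); B <- combine_leaf_stats(stats_b)
  empty_a <- all(vapply(A, nrow, integer(1)) == 0)
  empty_b <- all(vapply(B, nrow, integer(1)) == 0)
  if (empty_a || empty_b) stop("both groups must contain leaves")
  rows <- list()
  add <- function(statistic, class, va, vb, tested = TRUE, note = NA_character_) {
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (tested && length(va) && length(vb)) {
      w <- wilcoxon_ranksum(va, vb)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        statistic = statistic, class = class, n_a = length(va), n_b = length(vb),
        W = w$statistic, p_value = w$p_value, method = w$method,
        tested = TRUE, note = note)
    } else {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        statistic = statistic, class = class, n_a = length(va), n_b = length(vb),
        W = NA_real_, p_value = NA_real_, method = NA_character_,
        tested = FALSE, note = note)
    }
  }
  mature_note <- paste("leaves are selected by their number of mature",
                       "trichomes, making this comparison meaningless")
  if (nrow(A$density) && nrow(B$density)) {
    for (k in TRICHOME_CLASSES) {
      add("density", k,
          A$density$density_per_um2[A$density$class == k],
          B$density$density_per_um2[B$density$class == k],
          tested = k != 4L, note = if (k == 4L) mature_note else NA_character_)
    }
  }
  if (nrow(A$trichome) && nrow(B$trichome)) {
    for (col in c("voronoi2d_um2", "voronoi3d_um2")) {
      nm <- if (col == "voronoi2d_um2") "voronoi_2d_area" else "voronoi_3d_area"
      for (k in TRICHOME_CLASSES) {
        add(nm, k, A$trichome[[col]][A$trichome$class == k],
            B$trichome[[col]][B$trichome$class == k],
            tested = k != 4L, note = if (k == 4L) mature_note else NA_character_)
      }
    }
    add("nn_geodesic", NA_integer_,
        A$trichome$nn_geodesic_um, B$trichome$nn_geodesic_um)
  }
  if (nrow(A$morpho) && nrow(B$morpho)) {
    add("leaf_area3d", NA_integer_, A$morpho$area3d_um2, B$morpho$area3d_um2)
    add("leaf_length", NA_integer_, A$morpho$length_um, B$morpho$length_um)
    add("leaf_index", NA_integer_, A$morpho$leaf_index, B$morpho$leaf_index)
  }
  tbl <- dplyr::bind_rows(rows)
  tbl$p_bh <- NA_real_
  tested <- which(tbl$tested)
  tbl$p_bh[tested] <- stats::p.adjust(tbl$p_value[tested], method = "BH")
  tbl$significant <- tbl$tested & !is.na(tbl$p_value) & tbl$p_value < alpha
  structure(list(table = tbl, alpha = alpha,
                 genotype_a = A$morpho$genotype[1] %||% A$density$genotype[1],
                 genotype_b = B$morpho$genotype[1] %||% B$density$genotype[1]),
            class = "genotype_comparison")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' @export
print.genotype_comparison <- function(x, ...) {
  cat(sprintf("<genotype_comparison> %s vs %s (alpha = %g)\n",
              x$genotype_a, x$genotype_b, x$alpha))
  print(as.data.frame(x$table[c("statistic", "class", "n_a", "n_b",
                                "p_value", "significant", "tested")]),
        digits = 4)
  invisible(x)
}

#' Tidy a genotype comparison into its test table
#' @param x a `genotype_comparison`.
#' @param ... unused.
#' @return tibble, one row per (statistic, class) test.
#' @export
tidy.genotype_comparison <- function(x, ...) x$table

#' One-row summary of a genotype comparison
#' @param x a `genotype_comparison`.
#' @param ... unused.
#' @export
glance.genotype_comparison <- function(x, ...) {
  tibble::tibble(n_tests = sum(x$table$tested),
                 n_significant = sum(x$table$significant),
                 alpha = x$alpha,
                 min_p = suppressWarnings(min(x$table$p_value, na.rm = TRUE)))
}
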