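# Pipeline drivers: simulate a fixture scene, reconstruct a leaf surface from
# a stack, and analyze annotated leaves. These back the command-line script
# in inst/cli/leafsurf.R; all outputs are plain text/TIFF so runs are
# bit-reproducible under a fixed seed.

#' Default run configuration
#'
#' Nested named list with every tunable of the pipeline: calibration
#' (`um_per_px`; either `um_per_slice` or the reference-object triplet
#' `ref_thickness_um`, `ref_idx_bottom`, `ref_idx_top`), focus (`window`),
#' segmentation (`polarity`, `disc_radius_px`), elastic map (`grid`,
#' `lambda`, `mu`, `tol`, `max_iter`, `subsample`), stats (`n_bins`,
#' `alpha`), scene (passed to [synthetic_scene()]), and `seed`.
#'
#' @param ... overrides merged over the defaults (named, possibly nested).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    calibration = list(um_per_px = 2, um_per_slice = 3.4),
    focus = list(window = 5L),
    segmentation = list(polarity = "dark", disc_radius_px = 8L),
    elastic_map = list(grid = c(25L, 25L), lambda = 1e-4, mu = 1e-3,
                       tol = 1e-5, max_iter = 100L, subsample = 2L),
    stats = list(n_bins = 10L, alpha = 0.05),
    scene = list(surface = "gaussian_bump", shape = c(200L, 200L),
                 n_slices = 60L, n_per_class = c(3L, 3L, 3L, 3L),
                 min_spacing_um = 30)
  )
  utils::modifyList(cfg, list(...))
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(run_config(),
                           jsonlite::read_json(path, simplifyVector = TRUE))
  validate_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

validate_config <- function(cfg) {
  cal <- cfg$calibration
  if (is.null(cal$um_per_px) || cal$um_per_px <= 0)
    stop("config error: calibration$um_per_px must be positive")
  if (is.null(cal$um_per_slice) &&
      (is.null(cal$ref_thickness_um) || is.null(cal$ref_idx_bottom) ||
         is.null(cal$ref_idx_top)))
    stop("config error: give um_per_slice or the reference-object triplet")
  if (cfg$elastic_map$lambda < 0 || cfg$elastic_map$mu < 0)
    stop("config error: lambda and mu must be >= 0")
  if (cfg$focus$window %% 2L != 1L) stop("config error: focus window must be odd")
  invisible(cfg)
}

config_calibration <- function(cfg) {
  cal <- cfg$calibration
  ups <- cal$um_per_slice
  if (is.null(ups))
    ups <- calibrate_z(cal$ref_thickness_um, cal$ref_idx_bottom, cal$ref_idx_top)
  calibration(cal$um_per_px, ups)
}

write_provenance <- function(out_dir, cfg, extra = list()) {
  jsonlite::write_json(
    c(list(package = "leafsurf",
           version = as.character(utils::packageVersion("leafsurf")),
           r_version = paste(R.version$major, R.version$minor, sep = "."),
           config = cfg),
      extra),
    file.path(out_dir, "provenance.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a fixture: render a stack and sample trichome annotations
#'
#' Writes `stack.tif` (multi-page 16-bit), `annotations.csv` + `frame.csv`,
#' `truth_height.csv` (ground-truth surface) and a provenance record.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a named list of the written paths plus the scene.
#' @export
run_simulate <- function(cfg = run_config(), out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- cfg$scene
  n_slices <- sc$n_slices %||% 60L
  ups <- config_calibration(cfg)$um_per_slice
  scene <- synthetic_scene(
    surface = sc$surface %||% "gaussian_bump",
    shape = sc$shape %||% c(200L, 200L),
    um_per_px = cfg$calibration$um_per_px,
    um_per_slice = ups,
    params = list(z0_um = 0.15 * (n_slices - 1) * ups,
                  amp_um = 0.6 * (n_slices - 1) * ups),
    seed = cfg$seed)
  rs <- render_stack(scene, n_slices = n_slices)
  paths <- list(stack = file.path(out_dir, "stack.tif"),
                annotations = file.path(out_dir, "annotations.csv"),
                frame = file.path(out_dir, "frame.csv"),
                truth = file.path(out_dir, "truth_height.csv"))
  write_stack(rs$stack, paths$stack)
  leaf <- sample_pattern(
    scene$mask, n_per_class = sc$n_per_class %||% c(3L, 3L, 3L, 3L),
    min_spacing_um = sc$min_spacing_um %||% 30,
    um_per_px = scene$um_per_px,
    genotype = sc$genotype %||% "wt", leaf_id = sc$leaf_id %||% "leaf1",
    seed = cfg$seed)
  write_annotations(leaf, paths$annotations, paths$frame)
  utils::write.csv(
    data.frame(x_px = rep(0:(scene$shape[2] - 1), each = scene$shape[1]),
               y_px = rep(0:(scene$shape[1] - 1), times = scene$shape[2]),
               z_um = as.vector(rs$truth$z_um)),
    paths$truth, row.names = FALSE)
  write_provenance(out_dir, cfg, list(stage = "simulate", seed = cfg$seed))
  invisible(c(paths, list(scene = scene, leaf = leaf)))
}

#' Reconstruct the 3D leaf surface from a focus stack
#'
#' Runs the whole reconstruction: read stack, height map, sharp image, leaf
#' segmentation, point cloud, elastic-map fit, triangulation. Writes
#' `height_map.tif`, `sharp.tif`, `mask.tif`, `boundary.csv`,
#' `elastic_map.json`, `mesh.ply`, an energy trace and a provenance record.
#'
#' @param stack_path path to the stack (multi-page TIFF, or vector of paths).
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @return invisibly, list with the in-memory objects (`stack`, `hm`,
#'   `sharp`, `mask`, `map`, `mesh`) and written paths.
#' @export
run_reconstruct <- function(stack_path, cfg = run_config(), out_dir) {
  validate_config(cfg)
  for (p in stack_path) if (!file.exists(p))
    stop("stack file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cal <- config_calibration(cfg)
  stack <- read_stack(stack_path, calibration = cal)
  hm <- compute_height_map(stack, window = cfg$focus$window)
  sharp <- compose_sharp_image(stack, hm)
  mask <- segment_leaf(sharp, disc_radius_px = cfg$segmentation$disc_radius_px,
                       polarity = cfg$segmentation$polarity)
  cloud <- build_cloud(hm, mask, cal, subsample = cfg$elastic_map$subsample)
  map <- fit_elastic_map(cloud, grid_shape = cfg$elastic_map$grid,
                         lambda = cfg$elastic_map$lambda,
                         mu = cfg$elastic_map$mu,
                         tol = cfg$elastic_map$tol,
                         max_iter = cfg$elastic_map$max_iter)
  mesh <- triangulate(map)
  write_height_map(hm, file.path(out_dir, "height_map.tif"))
  write_image(sharp, file.path(out_dir, "sharp.tif"))
  write_leaf_mask(mask, file.path(out_dir, "mask.tif"))
  write_leaf_mask(mask, file.path(out_dir, "boundary.csv"))
  write_elastic_map(map, file.path(out_dir, "elastic_map.json"))
  write_mesh(mesh, file.path(out_dir, "mesh.ply"))
  utils::write.csv(data.frame(iteration = seq_along(map$energy_trace),
                              total_energy = map$energy_trace),
                   file.path(out_dir, "energy_trace.csv"), row.names = FALSE)
  write_provenance(out_dir, cfg, list(stage = "reconstruct"))
  invisible(list(stack = stack, hm = hm, sharp = sharp, mask = mask,
                 map = map, mesh = mesh, out_dir = out_dir))
}

#' Patterning statistics and genotype comparison for annotated leaves
#'
#' Takes a manifest of reconstructed, annotated leaves; applies the
#' mature-trichome selection rule (failures are reported, not silently
#' dropped); builds per-genotype meta leaves, longitudinal profiles, class
#' histograms, per-leaf statistics; and, with exactly two genotypes, the
#' Wilcoxon comparison report. All tables are written as CSV.
#'
#' @param manifest data frame, one row per leaf: `leaf_id`, `genotype`,
#'   `annotations` (CSV path), `frame` (CSV path), `map` (elastic-map JSON),
#'   `mask` (mask TIFF). In-memory equivalents can be supplied via `leaves`.
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @param leaves optional list of prepared `list(leaf=, mesh=, mask=)`
#'   entries, bypassing file loading (used by tests).
#' @return invisibly, list with `stats` (per-genotype `leaf_stats`),
#'   `metaleaf`, `excluded` and (two genotypes) the `comparison`.
#' @export
run_stats <- function(manifest = NULL, cfg = run_config(), out_dir,
                      leaves = NULL) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  upp <- cfg$calibration$um_per_px
  if (is.null(leaves)) {
    leaves <- lapply(seq_len(nrow(manifest)), function(r) {
      row <- manifest[r, ]
      leaf <- load_annotations(row$annotations, row$frame, um_per_px = upp)
      leaf$leaf_id <- row$leaf_id
      leaf$genotype <- row$genotype
      map <- read_elastic_map(row$map)
      mk <- read_tiff_gray(row$mask)
      mask <- leaf_mask(mk$pages[[1]] > 0)
      list(leaf = leaf, mesh = triangulate(map), mask = mask)
    })
  }
  sel <- vapply(leaves, function(l) select_leaf(l$leaf), logical(1))
  excluded <- purrr::map_dfr(leaves[!sel], function(l) tibble::tibble(
    leaf_id = l$leaf$leaf_id, genotype = l$leaf$genotype,
    n_mature = sum(l$leaf$trichomes$class == 4L),
    reason = "mature-trichome count outside 1..6"))
  utils::write.csv(as.data.frame(excluded), file.path(out_dir, "excluded.csv"),
                   row.names = FALSE)
  leaves <- leaves[sel]
  if (!length(leaves)) stop("selection error: no leaf passes the selection rule")

  genos <- vapply(leaves, function(l) as.character(l$leaf$genotype), character(1))
  meta <- build_metaleaf(lapply(leaves, `[[`, "leaf"))
  utils::write.csv(as.data.frame(meta), file.path(out_dir, "metaleaf.csv"),
                   row.names = FALSE)
  prof <- purrr::map_dfr(unique(genos), function(g) {
    p <- longitudinal_profile(meta[meta$genotype == g, ],
                              n_bins = cfg$stats$n_bins)
    p$genotype <- g
    p
  })
  utils::write.csv(as.data.frame(prof), file.path(out_dir, "profile.csv"),
                   row.names = FALSE)
  hist <- purrr::map_dfr(unique(genos), function(g) {
    h <- metaleaf_histogram(meta[meta$genotype == g, ],
                            grid = c(cfg$stats$n_bins, cfg$stats$n_bins))
    h$genotype <- g
    h
  })
  utils::write.csv(as.data.frame(hist), file.path(out_dir, "histogram.csv"),
                   row.names = FALSE)
  bdist <- purrr::map_dfr(leaves, function(l) tibble::tibble(
    leaf_id = l$leaf$leaf_id, genotype = l$leaf$genotype,
    base_distance(l$leaf)))
  utils::write.csv(as.data.frame(bdist), file.path(out_dir, "base_distance.csv"),
                   row.names = FALSE)
  dist_prof <- purrr::map_dfr(leaves, function(l) tibble::tibble(
    leaf_id = l$leaf$leaf_id, genotype = l$leaf$genotype,
    distortion_map(l$mesh, n_bins = cfg$stats$n_bins)$profile))
  utils::write.csv(as.data.frame(dist_prof), file.path(out_dir, "distortion_profile.csv"),
                   row.names = FALSE)

  per_geno <- lapply(split(seq_along(leaves), genos), function(ix)
    combine_leaf_stats(lapply(leaves[ix], function(l)
      leaf_statistics(l$leaf, l$mesh, l$mask, um_per_px = upp))))
  all_stats <- combine_leaf_stats(unname(per_geno))
  utils::write.csv(as.data.frame(all_stats$density),
                   file.path(out_dir, "density.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(all_stats$trichome),
                   file.path(out_dir, "voronoi_nn.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(all_stats$morpho),
                   file.path(out_dir, "morphometrics.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(class_abundance(lapply(leaves, `[[`, "leaf"))),
                   file.path(out_dir, "class_abundance.csv"), row.names = FALSE)

  comparison <- NULL
  if (length(per_geno) == 2) {
    comparison <- compare_genotypes(per_geno[[1]], per_geno[[2]],
                                    alpha = cfg$stats$alpha)
    utils::write.csv(as.data.frame(tidy(comparison)),
                     file.path(out_dir, "comparison.csv"), row.names = FALSE)
    txt <- utils::capture.output(print(comparison))
    writeLines(txt, file.path(out_dir, "report.txt"))
  }
  write_provenance(out_dir, cfg, list(stage = "stats"))
  invisible(list(stats = per_geno, metaleaf = meta, excluded = excluded,
                 comparison = comparison))
}
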