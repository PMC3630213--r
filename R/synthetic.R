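# Synthetic scenes: textured surfaces imaged with depth-dependent defocus
# blur, plus hard-core trichome point patterns — ground truth for every
# pipeline stage.
#
# Default physical world: a young leaf roughly 320 um long imaged at
# 2 um/px with a 10x objective, 60 z-slices at 3.4 um/slice (a 170 um
# cover-slide fragment spanning 50 slices), leaf darker than the agar
# background in bright field. Defocus is modeled as a Gaussian blur whose
# sigma grows linearly with distance from the focal plane:
# sigma(z) = sigma0 + k * |z - h|, in pixels, z and h in slices.

run_with_seed <- function(seed, code) {
  if (is.null(seed)) return(code())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code()
}

# Dense separable Gaussian blur with edge renormalization.
gauss_row_mat <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  d <- outer(seq_len(n), seq_len(n), "-")
  G <- exp(-d^2 / (2 * sigma^2)) * (abs(d) <= r)
  G / rowSums(G)
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  gauss_row_mat(nrow(img), sigma) %*% img %*% t(gauss_row_mat(ncol(img), sigma))
}

#' Define a synthetic microscope scene
#'
#' A surface from a named family, a band-limited random texture, an optional
#' elliptical leaf mask (leaf darker than background), and a linear
#' defocus-blur model with ground truth available for every pixel.
#'
#' @param surface one of `"plane"`, `"tilted_plane"`, `"gaussian_bump"`,
#'   `"cylinder"`, `"hemisphere"`.
#' @param shape image `(H, W)` in pixels (default `c(200, 200)`).
#' @param um_per_px lateral scale (default 2).
#' @param um_per_slice axial scale (default 3.4, a 170 um reference over 50
#'   slices).
#' @param params surface family parameters (amplitude `amp_um`, base height
#'   `z0_um`, tilt `ax`/`ay` in um/um, radius `radius_um`, bump width
#'   `width_um`); family-specific defaults fill the stack range.
#' @param sigma0 in-focus blur in pixels (default 0.5).
#' @param blur_k defocus growth, pixels per slice of defocus (default 0.3).
#' @param texture_contrast peak-to-peak texture amplitude on `[0,1]`
#'   intensities (default 0.5).
#' @param texture_scale_px correlation length of the texture (default 2 px).
#' @param mask `"ellipse"` (leaf covering ~80% of the frame) or `"none"`.
#' @param leaf_level,bg_level mean intensities of leaf and background
#'   (defaults 0.35 and 0.75: bright-field leaf darker than agar).
#' @param seed RNG seed; the same seed renders bit-identical scenes.
#' @return a `synthetic_scene`: ground-truth `h_um` (H x W), `texture`,
#'   `mask` (`leaf_mask` or NULL), calibration and blur parameters.
#' @export
synthetic_scene <- function(surface = "gaussian_bump", shape = c(200L, 200L),
                            um_per_px = 2, um_per_slice = 3.4,
                            params = list(), sigma0 = 0.5, blur_k = 0.3,
                            texture_contrast = 0.5, texture_scale_px = 2,
                            mask = c("ellipse", "none"),
                            leaf_level = 0.35, bg_level = 0.75, seed = 1L) {
  mask <- match.arg(mask)
  stopifnot(sigma0 >= 0, blur_k > 0)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  xs <- (seq_len(W) - 1) * um_per_px
  ys <- (seq_len(H) - 1) * um_per_px
  cx <- mean(range(xs)); cy <- mean(range(ys))
  ext <- min(diff(range(xs)), diff(range(ys)))
  p <- utils::modifyList(list(
    z0_um = 0.15 * 60 * um_per_slice,
    amp_um = 0.6 * 60 * um_per_slice,
    ax = 0.15, ay = 0.15,
    width_um = 0.25 * ext,
    radius_um = 0.55 * ext
  ), params)
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)
  h <- switch(surface,
    plane = matrix(p$z0_um + p$amp_um / 2, H, W),
    tilted_plane = p$z0_um + p$ax * (X - xs[1]) + p$ay * (Y - ys[1]),
    gaussian_bump = p$z0_um + p$amp_um *
      exp(-((X - cx)^2 + (Y - cy)^2) / (2 * p$width_um^2)),
    cylinder = p$z0_um + sqrt(pmax(p$radius_um^2 - (X - cx)^2, 0)) -
      sqrt(max(p$radius_um^2 - (0.45 * ext)^2, 0)),
    hemisphere = p$z0_um + sqrt(pmax(p$radius_um^2 - (X - cx)^2 - (Y - cy)^2, 0)),
    stop("unknown surface family: ", surface)
  )
  lm <- NULL
  if (mask == "ellipse") {
    a <- 0.42 * diff(range(xs)) / um_per_px
    b <- 0.46 * diff(range(ys)) / um_per_px
    mm <- ((col(h) - 1 - (W - 1) / 2) / a)^2 + ((row(h) - 1 - (H - 1) / 2) / b)^2 <= 1
    lm <- leaf_mask(mm)
    h[!mm] <- p$z0_um   # background: flat agar plane at the base height
  }
  tex <- run_with_seed(seed, function() {
    noise <- matrix(stats::runif(H * W), H, W)
    sm <- gaussian_blur(noise, texture_scale_px)
    sm <- (sm - mean(sm)) / max(abs(sm - mean(sm)))
    level <- if (is.null(lm)) leaf_level else ifelse(lm$mask, leaf_level, bg_level)
    pmin(pmax(level + texture_contrast / 2 * sm, 0), 1)
  })
  structure(list(surface = surface, h_um = h, texture = tex, mask = lm,
                 um_per_px = um_per_px, um_per_slice = um_per_slice,
                 sigma0 = sigma0, blur_k = blur_k,
                 texture_contrast = texture_contrast, params = p, seed = seed,
                 shape = c(H, W)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s, %d x %d px, h in [%.1f, %.1f] um\n",
              x$surface, x$shape[1], x$shape[2], min(x$h_um), max(x$h_um)))
  invisible(x)
}

#' Render a focus stack from a synthetic scene
#'
#' Slice `z` is the texture blurred pixel-wise with
#' `sigma(z) = sigma0 + k |z - h|` (slices), approximated by interpolation
#' over a ladder of uniformly blurred copies (ladder step 0.25 px).
#'
#' @param scene a [synthetic_scene()].
#' @param n_slices number of slices; the z range `0..n_slices-1` must cover
#'   the surface heights.
#' @return list with `stack` (a calibrated [image_stack()]) and `truth`
#'   (list: `z_slices` continuous ground-truth heights in slice units,
#'   `z_um`).
#' @export
render_stack <- function(scene, n_slices = 60L) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 2L) stop("n_slices must be >= 2")
  hs <- scene$h_um / scene$um_per_slice
  if (min(hs) < 0 || max(hs) > n_slices - 1L)
    stop("coverage error: slice range 0..", n_slices - 1,
         " does not cover surface heights ", round(min(hs), 2), "..",
         round(max(hs), 2), " (slices)")
  smax <- scene$sigma0 + scene$blur_k * max(
    max(hs), (n_slices - 1) - min(hs))
  ladder <- seq(scene$sigma0, smax + 0.25, by = 0.25)
  blurred <- lapply(ladder, function(s) gaussian_blur(scene$texture, s))
  H <- scene$shape[1]; W <- scene$shape[2]
  arr <- array(0, dim = c(H, W, n_slices))
  for (z in seq_len(n_slices) - 1L) {
    sg <- scene$sigma0 + scene$blur_k * abs(z - hs)
    fi <- (sg - ladder[1]) / 0.25
    lo <- pmin(floor(fi) + 1L, length(ladder) - 1L)
    tfrac <- fi - (lo - 1L)
    lo_v <- matrix(0, H, W); hi_v <- matrix(0, H, W)
    for (lev in unique(as.vector(lo))) {
      selm <- lo == lev
      lo_v[selm] <- blurred[[lev]][selm]
      hi_v[selm] <- blurred[[lev + 1L]][selm]
    }
    arr[, , z + 1L] <- (1 - tfrac) * lo_v + tfrac * hi_v
  }
  stack <- image_stack(arr, calibration = calibration(scene$um_per_px,
                                                      scene$um_per_slice))
  list(stack = stack,
       truth = list(z_slices = hs, z_um = scene$h_um))
}

#' Sample a hard-core trichome point pattern with developmental zones
#'
#' Points are drawn uniformly inside the mask, rejected below the minimum
#' spacing (capped rejection sampling). Classes occupy longitudinal zones:
#' class 1 (initiation) nearest the leaf base, class 4 (mature) nearest the
#' tip, with adjustable band overlap — mirroring the developmental zonation
#' of young leaves.
#'
#' @param mask a `leaf_mask`.
#' @param n_per_class integer counts for classes 1-4.
#' @param min_spacing_um hard-core minimum distance (micrometres); 0 gives a
#'   plain uniform pattern.
#' @param um_per_px lateral scale.
#' @param frame optional `leaf_frame` (micrometres); default: origin at the
#'   mask's basal end (min y on the mask's vertical midline), tip at the top.
#' @param overlap fractional widening of each class band (0 = fully separated
#'   zones; default 0.25).
#' @param genotype,leaf_id labels stored in the annotations.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling cap per point (default 2000).
#' @return an `annotated_leaf` (see [load_annotations()]).
#' @export
sample_pattern <- function(mask, n_per_class = c(3L, 3L, 3L, 3L),
                           min_spacing_um = 0, um_per_px = 1, frame = NULL,
                           overlap = 0.25, genotype = "wt", leaf_id = "leaf1",
                           seed = NULL, max_tries = 2000L) {
  stopifnot(length(n_per_class) == 4, all(n_per_class >= 0))
  idx <- which(mask$mask)
  if (!length(idx)) stop("empty mask")
  H <- nrow(mask$mask)
  px <- (idx - 1L) %/% H   # 0-based x
  py <- (idx - 1L) %% H    # 0-based y
  if (is.null(frame)) {
    basex <- stats::median(px[py == min(py)])
    tipx <- stats::median(px[py == max(py)])
    frame <- leaf_frame(c(basex, min(py)) * um_per_px,
                        c(tipx, max(py)) * um_per_px)
  }
  y0 <- min(py); y1 <- max(py)
  run_with_seed(seed, function() {
    acc_x <- numeric(0); acc_y <- numeric(0)
    cls <- integer(0); ids <- integer(0)
    tid <- 0L
    for (k in 1:4) {
      lo <- max((k - 1) / 4 - overlap / 4, 0)
      hi <- min(k / 4 + overlap / 4, 1)
      band <- idx[(py - y0) / max(y1 - y0, 1) >= lo &
                    (py - y0) / max(y1 - y0, 1) <= hi]
      if (!length(band) && n_per_class[k] > 0)
        stop("sampling error: empty zone for class ", k)
      for (r in seq_len(n_per_class[k])) {
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          s <- band[sample.int(length(band), 1L)]
          cand_x <- ((s - 1L) %/% H + stats::runif(1, -0.5, 0.5)) * um_per_px
          cand_y <- ((s - 1L) %% H + stats::runif(1, -0.5, 0.5)) * um_per_px
          if (!length(acc_x) || min_spacing_um <= 0 ||
              min(sqrt((acc_x - cand_x)^2 + (acc_y - cand_y)^2)) >= min_spacing_um) {
            tid <- tid + 1L
            acc_x <- c(acc_x, cand_x); acc_y <- c(acc_y, cand_y)
            cls <- c(cls, k); ids <- c(ids, tid)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("sampling error: min_spacing ", min_spacing_um,
               " um infeasible for class ", k, " after ", max_tries, " tries")
      }
    }
    tr <- tibble::tibble(trichome_id = ids, class = cls,
                         x_px = acc_x / um_per_px, y_px = acc_y / um_per_px,
                         x_um = acc_x, y_um = acc_y)
    structure(list(trichomes = tr, frame = frame, genotype = genotype,
                   leaf_id = leaf_id, um_per_px = um_per_px),
              class = "annotated_leaf")
  })
}
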