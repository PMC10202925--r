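#' Specification for a synthetic fluorescence micrograph
#'
#' Describes one synthetic single-channel scene with exact ground truth,
#' emulating the two regimes common in fluorescence counting data: evenly
#' distributed, well separated cells (microglia-like), and dense scenes with
#' touching/overlapping cells, speckle artifacts and uneven illumination
#' (public benchmark-like). Cells are rendered as Gaussian-smoothed ellipses
#' with jittered intensity; artifacts are sub-threshold speckles and
#' oversized smears that exercise the size filter.
#'
#' @param width,height Image size in pixels.
#' @param n_cells Number of true cells.
#' @param radius_range Min/max equivalent radius of a cell (px).
#' @param intensity_range Min/max peak intensity of a cell, on \[0, 1\].
#' @param background Constant background level on \[0, 1\].
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param overlap_fraction Proportion of cells placed as touching pairs
#'   (center distance uniform in 1.2--1.8 mean radii), in \[0, 1\].
#' @param eccentricity_max Maximum ellipse axis ratio (>= 1).
#' @param n_speckles Number of tiny bright artifacts (area below any
#'   reasonable `min_size`).
#' @param n_smears Number of large dim smears (area above `max_size`-scale).
#' @param gradient Multiplicative horizontal illumination gradient
#'   (0.7x--1.3x) emulating highly variable intensity.
#' @param bit_depth Output bit depth, 8 or 16.
#' @param seed Integer seed; fixes the scene exactly.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(width = 256L, height = 256L, n_cells = 50L,
                           radius_range = c(5, 8),
                           intensity_range = c(0.6, 0.9),
                           background = 0.1, noise_sd = 0.02,
                           overlap_fraction = 0, eccentricity_max = 1.5,
                           n_speckles = 0L, n_smears = 0L, gradient = FALSE,
                           bit_depth = 16L, seed = 1L) {
  if (any(radius_range <= 0) || radius_range[1] > radius_range[2])
    stop("radius_range must be positive and ordered")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]")
  if (eccentricity_max < 1) stop("eccentricity_max must be >= 1")
  if (intensity_range[1] > intensity_range[2] ||
      any(intensity_range < 0) || any(intensity_range > 1))
    stop("intensity_range must be ordered within [0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells),
                 radius_range = radius_range,
                 intensity_range = intensity_range,
                 background = background, noise_sd = noise_sd,
                 overlap_fraction = overlap_fraction,
                 eccentricity_max = eccentricity_max,
                 n_speckles = as.integer(n_speckles),
                 n_smears = as.integer(n_smears),
                 gradient = isTRUE(gradient),
                 bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Ellipse membership value: quadratic form <= 1 inside.
ellipse_q <- function(rowg, colg, cy, cx, a, b, theta) {
  dx <- colg - cx; dy <- rowg - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  (xr / a)^2 + (yr / b)^2
}

#' Generate a synthetic scene with exact ground truth
#'
#' Renders the scene described by a [synthetic_spec]: cells are placed by
#' rejection sampling (singletons kept apart by at least the sum of their
#' radii plus a 2 px guard; the requested fraction of cells arrives as
#' touching pairs), drawn as intensity-jittered ellipses, smoothed with a
#' 1 px Gaussian, overlaid with artifacts, optionally shaded by an
#' illumination gradient, and corrupted with additive Gaussian noise before
#' quantization to the requested bit depth. The ground-truth label image
#' assigns each pixel of a cell to the nearest covering cell, so every
#' marker (cell center) lies inside its own object's mask.
#'
#' @param spec A [synthetic_spec].
#' @param image_id Identifier for the produced image.
#' @return A `synthetic_scene`: list with `image` ([image_plane]), `markers`
#'   ([marker_set] of true centers), `truth_labels` (integer matrix),
#'   `truth` (per-cell data frame: `cell_id`, `x`, `y`, `radius_a`,
#'   `radius_b`, `theta`, `intensity`, `area`) and `spec`.
#' @export
generate_scene <- function(spec, image_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  rmax <- spec$radius_range[2]
  margin <- ceiling(rmax * spec$eccentricity_max) + 2
  if (2 * margin >= min(h, w)) stop("image too small for the requested radii")
  n <- spec$n_cells
  n_pair <- floor(spec$overlap_fraction * n / 2)
  centers <- matrix(numeric(0), 0, 2)  # (y, x)
  radii <- numeric(0)
  draw_radius <- function() stats::runif(1, spec$radius_range[1], spec$radius_range[2])
  place <- function(r, near = NULL) {
    for (attempt in 1:2000) {
      if (is.null(near)) {
        cy <- stats::runif(1, margin, h - margin)
        cx <- stats::runif(1, margin, w - margin)
      } else {
        d <- stats::runif(1, 1.2 * r, 1.8 * r)
        th <- stats::runif(1, 0, 2 * pi)
        cy <- near[1] + d * sin(th); cx <- near[2] + d * cos(th)
        if (cy < margin || cy > h - margin || cx < margin || cx > w - margin)
          next
      }
      if (nrow(centers)) {
        # singletons stay clear by the worst-case semi-major axes plus a
        # 4 px guard, so "non-touching" holds for any drawn eccentricity
        ecc <- sqrt(spec$eccentricity_max)
        dd <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        sep_ok <- if (is.null(near)) all(dd >= (radii + r) * ecc + 4) else {
          others <- dd[-nrow(centers)]
          length(others) == 0 || all(others >= (radii[-length(radii)] + r) * ecc + 4)
        }
        if (!sep_ok) next
      }
      return(c(cy, cx))
    }
    NULL
  }
  # paired (touching) placements first, then singletons; a greedy pass can
  # jam below the true packing capacity, so restart from scratch a few times
  # before declaring the packing infeasible
  for (restart in 1:8) {
    centers <- matrix(numeric(0), 0, 2); radii <- numeric(0)
    k <- 0L; pairs_done <- 0L; failed <- FALSE
    while (k < n) {
      r1 <- draw_radius()
      p1 <- place(r1)
      if (is.null(p1)) { failed <- TRUE; break }
      centers <- rbind(centers, p1); radii <- c(radii, r1); k <- k + 1L
      if (k < n && pairs_done < n_pair) {
        r2 <- draw_radius()
        p2 <- place(r2, near = p1)
        if (is.null(p2)) { failed <- TRUE; break }
        centers <- rbind(centers, p2); radii <- c(radii, r2); k <- k + 1L
        pairs_done <- pairs_done + 1L
      }
    }
    if (!failed) break
  }
  if (failed)
    stop("infeasible packing: could not place ", n,
         " cells of radius up to ", rmax, " in ", h, "x", w)
  rowg <- matrix(rep(seq_len(h), w), h)
  colg <- matrix(rep(seq_len(w), each = h), h)
  ideal <- matrix(spec$background, h, w)
  labels <- matrix(0L, h, w)
  best_q <- matrix(Inf, h, w)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    ecc <- stats::runif(1, 1, spec$eccentricity_max)
    a <- radii[i] * sqrt(ecc)
    b <- radii[i] / sqrt(ecc)
    th <- stats::runif(1, 0, pi)
    int <- stats::runif(1, spec$intensity_range[1], spec$intensity_range[2])
    q <- ellipse_q(rowg, colg, centers[i, 1], centers[i, 2], a, b, th)
    inside <- q <= 1
    ideal[inside] <- pmax(ideal[inside], int)
    upd <- inside & q < best_q
    labels[upd] <- i
    best_q[upd] <- q[upd]
    truth[[i]] <- data.frame(cell_id = i,
                             x = centers[i, 2] - 1, y = centers[i, 1] - 1,
                             radius_a = a, radius_b = b, theta = th,
                             intensity = int, area = sum(inside))
  }
  # artifacts: bright speckles (1-2 px radius) and large dim smears
  if (spec$n_speckles > 0) for (s in seq_len(spec$n_speckles)) {
    cy <- stats::runif(1, 3, h - 3); cx <- stats::runif(1, 3, w - 3)
    r <- stats::runif(1, 0.8, 1.6)
    q <- ellipse_q(rowg, colg, cy, cx, r, r, 0)
    ideal[q <= 1] <- pmax(ideal[q <= 1],
                          stats::runif(1, spec$intensity_range[1], 1))
  }
  if (spec$n_smears > 0) for (s in seq_len(spec$n_smears)) {
    cy <- stats::runif(1, margin, h - margin)
    cx <- stats::runif(1, margin, w - margin)
    a <- stats::runif(1, 3, 5) * rmax
    b <- stats::runif(1, 1.5, 2.5) * rmax
    th <- stats::runif(1, 0, pi)
    q <- ellipse_q(rowg, colg, cy, cx, a, b, th)
    lvl <- spec$intensity_range[1] * stats::runif(1, 0.9, 1.1)
    ideal[q <= 1] <- pmax(ideal[q <= 1], lvl)
  }
  img <- gauss_smooth(ideal, 1)
  if (spec$gradient)
    img <- img * matrix(rep(seq(0.7, 1.3, length.out = w), each = h), h)
  img <- img + stats::rnorm(h * w, 0, spec$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  scale <- 2^spec$bit_depth - 1
  plane <- image_plane(round(img * scale), bit_depth = spec$bit_depth,
                       image_id = image_id)
  truth <- do.call(rbind, truth)
  mk <- if (n > 0)
    marker_set(truth$x, truth$y, image_shape = c(h, w), image_id = image_id)
  else marker_set(image_shape = c(h, w), image_id = image_id)
  structure(list(image = plane, markers = mk, truth_labels = labels,
                 truth = if (is.null(truth))
                   data.frame(cell_id = integer(), x = numeric(), y = numeric(),
                              radius_a = numeric(), radius_b = numeric(),
                              theta = numeric(), intensity = numeric(),
                              area = integer())
                 else truth,
                 spec = spec),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s: %d x %d px, %d true cell(s), seed %d\n",
              x$image$image_id, x$spec$height, x$spec$width,
              nrow(x$truth), x$spec$seed))
  invisible(x)
}

#' Training annotation mask from a synthetic scene
#'
#' Emulates sparse manual pixel labeling: samples `n_cell_px` pixels from the
#' interiors of the true cells (label 1) and `n_bg_px` pixels at least
#' `guard` px from any cell (label 2).
#'
#' Half of the background pixels are drawn from the near-boundary band
#' (within `2 * guard` of a cell), mimicking the practice of labeling the
#' halo around misclassified cell borders so the classifier learns tight
#' object boundaries.
#'
#' @param scene A [generate_scene] result.
#' @param n_cell_px,n_bg_px Number of labeled pixels per class.
#' @param guard Background standoff distance from cell masks (px).
#' @param seed Seed for the pixel sampling.
#' @return An [annotation_mask].
#' @export
scene_annotation <- function(scene, n_cell_px = 300L, n_bg_px = 300L,
                             guard = 1L, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  lab <- scene$truth_labels
  fg <- which(lab > 0L)
  dil <- as.matrix(EBImage::dilate((lab > 0L) * 1, disk_kernel(guard)))
  band <- as.matrix(EBImage::dilate((lab > 0L) * 1, disk_kernel(2L * guard + 1L)))
  bg <- which(dil == 0)
  bg_near <- which(dil == 0 & band > 0)
  if (!length(fg) || !length(bg))
    stop("scene has no labelable cell or background pixels")
  m <- matrix(0L, nrow(lab), ncol(lab))
  m[sample(fg, min(n_cell_px, length(fg)))] <- 1L
  n_near <- min(n_bg_px %/% 2L, length(bg_near))
  if (n_near > 0) m[sample(bg_near, n_near)] <- 2L
  m[sample(bg, min(n_bg_px - n_near, length(bg)))] <- 2L
  annotation_mask(m, image_id = scene$image$image_id)
}

#' Generate a two-group synthetic experiment
#'
#' Produces two groups of scenes with (typically) differing true density,
#' emulating a control-vs-activated comparison. Each spec's `n_cells` is the
#' group mean: the per-image true count is drawn from a Poisson distribution
#' around it (truncated at mean + 4 standard deviations to keep placements
#' feasible), so replicate images vary the way biological fields of view do
#' and downstream ANOVA has within-group variance to work with. Image seeds
#' are derived deterministically from each spec's seed, so the whole dataset
#' is fixed by the two specs; two identical specs yield identical groups.
#'
#' @param specA,specB [synthetic_spec] for the two groups (their `n_cells`
#'   set the true mean densities).
#' @param n_images_per_group Images per group.
#' @param group_names Length-2 character vector of group labels.
#' @return A `synthetic_experiment`: list with `scenes` (named list),
#'   `table` (data frame: `image_id`, `group`, `true_count`,
#'   `density_per_px2`).
#' @export
generate_experiment <- function(specA, specB, n_images_per_group = 20L,
                                group_names = c("A", "B")) {
  stopifnot(inherits(specA, "synthetic_spec"), inherits(specB, "synthetic_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  scenes <- list(); rows <- list()
  for (g in 1:2) {
    spec <- if (g == 1) specA else specB
    cap <- spec$n_cells + ceiling(4 * sqrt(max(spec$n_cells, 1)))
    for (i in seq_len(n_images_per_group)) {
      s <- spec
      s$seed <- spec$seed + 7919L * i
      set.seed(s$seed)
      s$n_cells <- min(stats::rpois(1L, spec$n_cells), cap)
      id <- sprintf("%s_%02d", group_names[g], i)
      sc <- generate_scene(s, image_id = id)
      scenes[[id]] <- sc
      rows[[id]] <- data.frame(image_id = id, group = group_names[g],
                               true_count = nrow(sc$truth),
                               density_per_px2 = nrow(sc$truth) /
                                 (s$height * s$width))
    }
  }
  structure(list(scenes = scenes, table = do.call(rbind, rows)),
            class = "synthetic_experiment")
}

#' Write a synthetic fixture bundle to disk
#'
#' Standard on-disk layout consumed by the command-line stages: `images/`
#' (TIFF), `markers/` (CSV), `truth_masks/` (8-bit PNG label images) and
#' `truth_table.csv`.
#'
#' @param experiment A [generate_experiment] result (or a list of scenes).
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scene_bundle <- function(experiment, dir) {
  scenes <- if (inherits(experiment, "synthetic_experiment"))
    experiment$scenes else experiment
  for (sub in c("images", "markers", "truth_masks"))
    dir.create(file.path(dir, sub), showWarnings = FALSE, recursive = TRUE)
  for (sc in scenes) {
    id <- sc$image$image_id
    write_image(sc$image, file.path(dir, "images", paste0(id, ".tif")))
    write_markers(sc$markers, file.path(dir, "markers", paste0(id, ".csv")))
    lab <- pmin(sc$truth_labels, 255L)
    png::writePNG(lab / 255, file.path(dir, "truth_masks", paste0(id, ".png")))
  }
  if (inherits(experiment, "synthetic_experiment"))
    write_results_table(experiment$table, file.path(dir, "truth_table.csv"))
  invisible(dir)
}
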