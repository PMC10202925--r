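#' Threshold a probability map
#'
#' A pixel is foreground when its cell probability is greater than or equal
#' to the confidence threshold (inclusive comparison, so a map exactly at the
#' threshold is all foreground).
#'
#' @param prob_map Numeric matrix in \[0, 1\].
#' @param threshold Confidence threshold in \[0, 1\]; default 0.5.
#' @return Logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]")
  m <- as.matrix(prob_map) >= threshold
  structure(m, class = c("binary_mask", "matrix", "array"))
}

#' Separate touching objects by watershed
#'
#' Distance-transform watershed of the foreground: basins are grown from the
#' local maxima of the Euclidean distance map (maxima closer than 2 px merge
#' into one seed), and single-pixel-wide cut lines between distinct basins
#' are set to background. A convex single blob has one basin and is returned
#' unchanged; the operation can only ever increase the number of connected
#' components.
#'
#' @param mask Logical foreground matrix.
#' @return Logical matrix with cut lines removed.
#' @export
separate_touching <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(structure(mask, class = c("binary_mask", "matrix", "array")))
  d <- EBImage::distmap(mask * 1)
  w <- EBImage::watershed(d, tolerance = 1, ext = 2)
  w <- matrix(as.integer(w), nrow(mask), ncol(mask))
  # cut: foreground pixel with a different, smaller positive basin label in
  # its 8-neighborhood -> one-pixel line between basins; the 8-neighborhood
  # criterion keeps basins separated even under 8-connected labeling
  # (a 4-neighbor cut leaves diagonal staircase contacts that re-merge)
  cut <- matrix(FALSE, nrow(mask), ncol(mask))
  shifts8 <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                  c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  for (sh in shifts8) {
    nb <- shift_int(w, sh[1], sh[2])
    cut <- cut | (w > 0L & nb > 0L & nb != w & w > nb)
  }
  out <- mask & !cut
  structure(out, class = c("binary_mask", "matrix", "array"))
}

# integer shift with zero fill (labels outside the image count as background)
shift_int <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- x[rs + dr, cs + dc]
  out
}

# Connected-component labeling by iterative minimum-label propagation,
# supporting both 4- and 8-connectivity (EBImage::bwlabel is 4-only).
label_components <- function(mask, connectivity = 8L) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)          # provisional label = linear pixel index
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  big <- .Machine$integer.max
  repeat {
    cur <- lab
    for (sh in shifts) {
      nb <- shift_int(lab, sh[1], sh[2])
      nb[nb == 0L] <- big
      upd <- mask & nb < lab
      lab[upd] <- nb[upd]
    }
    if (identical(lab, cur)) break
  }
  # renumber components 1..k ordered by (min row, min col) of the component
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    comp <- match(lab, ids)
    comp[is.na(comp)] <- 0L
    min_row <- tapply(row(lab)[lab > 0L], comp[lab > 0L], min)
    min_col <- tapply(col(lab)[lab > 0L], comp[lab > 0L], min)
    ord <- order(min_row, min_col)
    relab <- integer(length(ids)); relab[ord] <- seq_along(ids)
    idx <- comp; idx[idx == 0L] <- NA_integer_
    newlab <- relab[idx]; newlab[is.na(newlab)] <- 0L
    lab <- matrix(newlab, nr, nc)
  }
  storage.mode(lab) <- "integer"
  lab
}

#' Label connected foreground components as cell objects
#'
#' Groups foreground pixels into maximal connected components under the
#' chosen connectivity. Object ids are deterministic: components are numbered
#' by the (min row, min col) of their pixel set.
#'
#' @param mask Logical foreground matrix.
#' @param connectivity 4 or 8 (default 8, the common binary-image convention).
#' @return A `cell_objects` object: list with `labels` (integer matrix, 0 =
#'   background), `table` (data frame `object_id`, `area`, `centroid_x`,
#'   `centroid_y`, bounding box columns) and `connectivity`.
#' @export
label_objects <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- label_components(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) {
    tab <- data.frame(object_id = integer(), area = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      min_row = integer(), min_col = integer(),
                      max_row = integer(), max_col = integer())
  } else {
    fg <- lab > 0L
    id <- lab[fg]
    rr <- row(lab)[fg]; cc <- col(lab)[fg]
    tab <- data.frame(
      object_id = seq_len(n),
      area = as.integer(tabulate(id, n)),
      centroid_x = as.numeric(tapply(cc, id, mean)) - 1,
      centroid_y = as.numeric(tapply(rr, id, mean)) - 1,
      min_row = as.integer(tapply(rr, id, min)) - 1L,
      min_col = as.integer(tapply(cc, id, min)) - 1L,
      max_row = as.integer(tapply(rr, id, max)) - 1L,
      max_col = as.integer(tapply(cc, id, max)) - 1L)
  }
  structure(list(labels = lab, table = tab,
                 connectivity = as.integer(connectivity)),
            class = "cell_objects")
}

#' @export
print.cell_objects <- function(x, ...) {
  cat(sprintf("<cell_objects> %d object(s), %d-connectivity, %d x %d px\n",
              nrow(x$table), x$connectivity, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' @export
length.cell_objects <- function(x) nrow(x$table)

#' Filter objects by size
#'
#' Keeps objects whose pixel area lies within the inclusive window
#' `[min_size, max_size]`; everything strictly smaller or strictly larger is
#' removed from both the table and the label image. Object ids of survivors
#' are preserved, so filtering is idempotent and the filtered set is always a
#' subset of the input.
#'
#' @param objects A [label_objects] result.
#' @param min_size,max_size Inclusive area bounds in pixels.
#' @return A `cell_objects` with the surviving objects.
#' @export
filter_by_size <- function(objects, min_size, max_size) {
  if (!(min_size > 0 && min_size <= max_size))
    stop("need 0 < min_size <= max_size")
  keep <- objects$table$area >= min_size & objects$table$area <= max_size
  drop_ids <- objects$table$object_id[!keep]
  lab <- objects$labels
  if (length(drop_ids)) lab[lab %in% drop_ids] <- 0L
  objects$labels <- lab
  objects$table <- objects$table[keep, , drop = FALSE]
  rownames(objects$table) <- NULL
  objects
}

#' Morphology of one cell object
#'
#' Computes the per-object morphology record: area, centroid, intensity
#' minimum/maximum/mean and skewness over the object's pixels, perimeter, and
#' circularity 4*pi*A/P^2 clamped to at most 1. The perimeter is the
#' crack-edge count (edges between object and non-object pixels, image border
#' included) scaled by pi/4, the standard bias correction that makes digital
#' disks measure close to their true circumference.
#'
#' @param objects A [label_objects] result.
#' @param image The source [image_plane] or matrix (raw intensity scale).
#' @param object_id Id of the object to measure, or `NULL` for all objects.
#' @return A data frame with one row per object: `object_id`, `area`,
#'   `centroid_x`, `centroid_y`, `min_intensity`, `max_intensity`,
#'   `mean_intensity`, `intensity_skewness`, `perimeter`, `circularity`.
#' @export
measure_morphology <- function(objects, image, object_id = NULL) {
  img <- if (inherits(image, "image_plane")) image$pixels else as.matrix(image)
  lab <- objects$labels
  stopifnot(all(dim(img) == dim(lab)))
  ids <- if (is.null(object_id)) objects$table$object_id else object_id
  # crack edges per object, image border counted as background
  edge_counts <- integer(max(lab, 1L))
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- shift_int(lab, sh[1], sh[2])
    boundary <- lab > 0L & nb != lab
    tcnt <- tabulate(lab[boundary], nbins = max(lab, 1L))
    edge_counts <- edge_counts + tcnt
  }
  rows <- lapply(ids, function(id) {
    sel <- lab == id
    if (!any(sel)) stop("no such object_id: ", id)
    v <- img[sel]
    n <- length(v)
    mu <- mean(v)
    m2 <- mean((v - mu)^2)
    skew <- if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0
    per <- edge_counts[id] * pi / 4
    circ <- min(4 * pi * n / per^2, 1)
    data.frame(object_id = id, area = n,
               centroid_x = mean(col(lab)[sel]) - 1,
               centroid_y = mean(row(lab)[sel]) - 1,
               min_intensity = min(v), max_intensity = max(v),
               mean_intensity = mu, intensity_skewness = skew,
               perimeter = per, circularity = circ)
  })
  if (!length(rows))
    return(data.frame(object_id = integer(), area = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      min_intensity = numeric(), max_intensity = numeric(),
                      mean_intensity = numeric(),
                      intensity_skewness = numeric(),
                      perimeter = numeric(), circularity = numeric()))
  do.call(rbind, rows)
}

#' Count cells in one image
#'
#' The full counting pipeline: feature stack, probability map, confidence
#' thresholding, optional watershed separation, connected-component labeling,
#' inclusive size filtering, and per-object morphology.
#'
#' @param image An [image_plane] (or matrix).
#' @param classifier A trained [train_pixel_classifier].
#' @param config An [analysis_config].
#' @param stack Optional precomputed [build_feature_stack] for this image
#'   (used by the ranking stage to avoid recomputation).
#' @return A `cell_count` object: list with `count`, `objects`
#'   ([label_objects] result after filtering), `morphology` (data frame),
#'   `prob_map`, and `image_id`.
#' @export
count_cells <- function(image, classifier, config = analysis_config(),
                        stack = NULL) {
  image <- as_image_plane(image)
  if (is.null(stack))
    stack <- build_feature_stack(image, classifier$feature_config)
  pm <- predict_probability(classifier, stack)
  mask <- binarize(pm, config$threshold)
  if (config$watershed) mask <- separate_touching(mask)
  objects <- label_objects(mask, config$connectivity)
  objects <- filter_by_size(objects, config$min_size, config$max_size)
  morph <- if (nrow(objects$table))
    measure_morphology(objects, image) else
    measure_morphology(objects, image, object_id = integer())
  structure(list(count = nrow(objects$table), objects = objects,
                 morphology = morph, prob_map = pm,
                 image_id = image$image_id),
            class = "cell_count")
}

#' @export
print.cell_count <- function(x, ...) {
  cat(sprintf("<cell_count> %s: %d cell(s)\n",
              if (nzchar(x$image_id)) x$image_id else "(unnamed)", x$count))
  invisible(x)
}
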