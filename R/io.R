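#' Single-channel image plane
#'
#' The unit of all processing: a 2D grid of non-negative intensities with an
#' optional physical pixel size. Pixels are stored as a base-R numeric matrix
#' indexed `[row, col]`; all user-facing coordinates are 0-based with
#' `x` = column and `y` = row, origin at the top-left.
#'
#' @param pixels Numeric matrix of intensities, all finite and >= 0.
#' @param bit_depth Either 8 or 16; the nominal intensity scale. May be `NULL`
#'   for images of unknown provenance (e.g. already normalized data).
#' @param pixel_size Optional physical side length of one pixel in micrometres.
#' @param image_id Optional identifier used to pair images with markers and
#'   masks; defaults to `""`.
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(pixels, bit_depth = NULL, pixel_size = NULL,
                        image_id = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1")
  if (any(!is.finite(pixels)))
    stop("image intensities must all be finite")
  if (any(pixels < 0))
    stop("image intensities must be non-negative")
  if (!is.null(bit_depth)) {
    bit_depth <- as.integer(bit_depth)
    if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  }
  if (!is.null(pixel_size) && (!is.finite(pixel_size) || pixel_size <= 0))
    stop("pixel_size must be a positive length (micrometres)")
  structure(list(pixels = pixels,
                 height = nrow(pixels), width = ncol(pixels),
                 bit_depth = bit_depth, pixel_size = pixel_size,
                 image_id = as.character(image_id)),
            class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %s: %d x %d px, bit depth %s, range [%g, %g]\n",
              if (nzchar(x$image_id)) x$image_id else "(unnamed)",
              x$height, x$width,
              if (is.null(x$bit_depth)) "unknown" else x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_plane <- function(x) c(x$height, x$width)

# Coerce matrices (and EBImage-style arrays) to image_plane.
as_image_plane <- function(x, image_id = "") {
  if (inherits(x, "image_plane")) return(x)
  image_plane(x, image_id = image_id)
}

#' Read a single-channel image
#'
#' Reads an 8- or 16-bit TIFF or PNG as an [image_plane]. Multi-channel files
#' are accepted only when all channels are identical (a grayscale image saved
#' as RGB); genuinely multi-channel images are rejected, since the counting
#' workflow is defined for single-channel data only.
#'
#' @param path Path to a `.tif`, `.tiff` or `.png` file.
#' @param image_id Identifier to attach; defaults to the file name stem.
#' @return An [image_plane] with intensities on the original integer scale
#'   (0..255 or 0..65535) and the recorded bit depth.
#' @export
read_image <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    bd <- attr(img, "bits.per.sample")
    if (is.null(bd)) bd <- if (max(img) > 255) 16L else 8L
  } else if (ext == "png") {
    img <- png::readPNG(path)
    bd <- png_bit_depth(path)
    img <- round(img * (2^bd - 1))
  } else {
    stop("unsupported image format '", ext, "': use TIFF or PNG")
  }
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    ref <- img[, , 1L]
    for (k in seq_len(nch)[-1L]) {
      if (!isTRUE(all.equal(ref, img[, , k], tolerance = 0)))
        stop("single-channel only: '", basename(path),
             "' has ", nch, " distinct channels")
    }
    img <- ref
  }
  image_plane(img, bit_depth = as.integer(bd), image_id = image_id)
}

# Bit depth straight from the PNG IHDR header (byte 25 of the file).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  as.integer(hdr[25L])
}

#' Write a single-channel image
#'
#' Inverse of [read_image]: writes integer intensities to TIFF or PNG at the
#' image's bit depth so that a read/write/read round trip is exact. PNG
#' output is limited to 8-bit data; 16-bit images go to TIFF.
#'
#' @param image An [image_plane] or numeric matrix of integers.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @export
write_image <- function(image, path) {
  image <- as_image_plane(image)
  bd <- if (is.null(image$bit_depth)) 16L else image$bit_depth
  scaled <- image$pixels / (2^bd - 1)
  if (any(scaled > 1)) stop("intensities exceed the image bit depth")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = bd)
  } else if (ext == "png") {
    # the PNG writer stores 8 bits per sample; 16-bit data must go to TIFF
    if (bd == 16L)
      stop("PNG output is 8-bit only; write 16-bit images as TIFF")
    png::writePNG(scaled, path)
  } else stop("unsupported image format '", ext, "'")
  invisible(path)
}

#' Manual cell markers for one image
#'
#' A set of manually placed count-marker points, one per cell body, in pixel
#' coordinates (`x` = column, `y` = row, 0-based). Fractional coordinates are
#' rounded half-up to the nearest pixel. Duplicate markers are kept and
#' flagged in the attached load report.
#'
#' @param x,y Numeric vectors of equal length.
#' @param image_shape Integer `c(height, width)` bounds the points must lie in
#'   after rounding; `NULL` skips the check.
#' @param image_id Identifier of the paired image.
#' @return A `marker_set`: data frame with integer columns `x`, `y`, attribute
#'   `image_id` and attribute `report` (list with `n_duplicates`).
#' @export
marker_set <- function(x = numeric(), y = numeric(), image_shape = NULL,
                       image_id = "") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  xi <- round_half_up(x)
  yi <- round_half_up(y)
  if (!is.null(image_shape)) {
    bad <- which(xi < 0L | xi >= image_shape[2] | yi < 0L | yi >= image_shape[1])
    if (length(bad))
      stop("marker(s) outside image bounds in row(s): ",
           paste(bad, collapse = ", "))
  }
  ms <- data.frame(x = xi, y = yi)
  dup <- duplicated(ms)
  attr(ms, "image_id") <- as.character(image_id)
  attr(ms, "report") <- list(n_duplicates = sum(dup))
  class(ms) <- c("marker_set", "data.frame")
  ms
}

round_half_up <- function(v) as.integer(floor(v + 0.5))

#' Read manual markers from CSV
#'
#' Expects a header `x,y` and one row per marker in pixel units. Rows falling
#' outside the image bounds after rounding abort the load with their row
#' numbers, so annotation errors surface immediately.
#'
#' @param path CSV file path.
#' @param image_shape Integer `c(height, width)` of the paired image.
#' @param image_id Identifier; defaults to the file name stem.
#' @return A [marker_set].
#' @export
read_markers <- function(path, image_shape, image_id = NULL) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("marker CSV must have columns 'x' and 'y': ", path)
  if (nrow(df) && (!is.numeric(df$x) || !is.numeric(df$y)))
    stop("marker coordinates must be numeric: ", path)
  marker_set(df$x, df$y, image_shape = image_shape, image_id = image_id)
}

#' Write markers to CSV
#' @param markers A [marker_set].
#' @param path Output CSV path.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(as.data.frame(markers)[, c("x", "y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a pixel annotation mask
#'
#' Annotation masks carry sparse training labels over the palette
#' 0 = unlabeled, 1 = cell, 2 = background, stored as a single-channel PNG or
#' TIFF whose raw gray values are the labels.
#'
#' @param path Mask image path.
#' @param image_shape Optional `c(height, width)` the mask must match.
#' @param image_id Identifier; defaults to the file name stem.
#' @return An `annotation_mask`: integer matrix with values in {0,1,2} and an
#'   `image_id` attribute.
#' @export
read_annotation_mask <- function(path, image_shape = NULL, image_id = NULL) {
  img <- read_image(path, image_id = image_id)
  annotation_mask(img$pixels, image_shape = image_shape,
                  image_id = img$image_id)
}

#' @rdname read_annotation_mask
#' @param labels Matrix of labels in {0,1,2}.
#' @export
annotation_mask <- function(labels, image_shape = NULL, image_id = "") {
  labels <- as.matrix(labels)
  if (!all(labels %in% c(0, 1, 2)))
    stop("annotation mask labels must be 0 (unlabeled), 1 (cell) or 2 (background)")
  if (!is.null(image_shape) && !all(dim(labels) == image_shape))
    stop("annotation mask dimensions ", paste(dim(labels), collapse = "x"),
         " do not match image ", paste(image_shape, collapse = "x"))
  storage.mode(labels) <- "integer"
  structure(labels, image_id = as.character(image_id),
            class = c("annotation_mask", "matrix", "array"))
}

#' Read a usable-area mask
#'
#' Marks the image region suitable for cell detection (nonzero = usable),
#' used to normalize counts to area when tissue defects exclude part of an
#' image, and optionally to exclude objects and markers from evaluation.
#'
#' @param path Mask image path (any nonzero pixel counts as usable).
#' @param image_shape Optional `c(height, width)` the mask must match.
#' @param image_id Identifier; defaults to the file name stem.
#' @return A logical matrix of class `usable_mask` with an `image_id`
#'   attribute; the usable fraction must be in (0, 1].
#' @export
read_usable_mask <- function(path, image_shape = NULL, image_id = NULL) {
  img <- read_image(path, image_id = image_id)
  usable_mask(img$pixels > 0, image_shape = image_shape,
              image_id = img$image_id)
}

#' @rdname read_usable_mask
#' @param usable Logical matrix (TRUE = usable).
#' @export
usable_mask <- function(usable, image_shape = NULL, image_id = "") {
  usable <- as.matrix(usable)
  storage.mode(usable) <- "logical"
  if (!any(usable)) stop("usable-area mask is entirely unusable")
  if (!is.null(image_shape) && !all(dim(usable) == image_shape))
    stop("usable mask dimensions do not match image")
  structure(usable, image_id = as.character(image_id),
            class = c("usable_mask", "matrix", "array"))
}

#' Analysis configuration
#'
#' Bundles every tunable of the counting pipeline. Defaults mirror the
#' workflow's standard settings: confidence threshold 0.5, object size window
#' 50--1000 px, 8-connectivity, watershed off (suited to evenly distributed,
#' non-touching cells; enable it for dense data with touching cells).
#'
#' @param threshold Minimum cell-class probability for a pixel to count as
#'   foreground, in \[0, 1\].
#' @param min_size,max_size Inclusive object-area bounds in pixels.
#' @param watershed Logical; split touching objects by distance-transform
#'   watershed before size filtering.
#' @param connectivity Pixel connectivity for object labeling, 4 or 8.
#' @param model_type `"random_forest"` or `"bayes"`.
#' @param seed Integer seed controlling all stochastic steps.
#' @param feature_config A [feature_config]; `NULL` selects the default
#'   feature families for `model_type`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(threshold = 0.5, min_size = 50, max_size = 1000,
                            watershed = FALSE, connectivity = 8,
                            model_type = c("random_forest", "bayes"),
                            seed = 1L, feature_config = NULL) {
  model_type <- match.arg(model_type)
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]")
  if (!(min_size > 0 && min_size <= max_size))
    stop("need 0 < min_size <= max_size")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (is.null(feature_config))
    feature_config <- feature_config(families = default_families(model_type))
  stopifnot(inherits(feature_config, "feature_config"))
  structure(list(threshold = threshold,
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 watershed = isTRUE(watershed),
                 connectivity = as.integer(connectivity),
                 model_type = model_type,
                 seed = as.integer(seed),
                 feature_config = feature_config),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  threshold %.3g | size [%d, %d] px | watershed %s | %d-connectivity\n",
              x$threshold, x$min_size, x$max_size,
              if (x$watershed) "on" else "off", x$connectivity))
  cat(sprintf("  model %s | seed %d | %d feature families\n",
              x$model_type, x$seed, length(x$feature_config$families)))
  invisible(x)
}

#' Read or write a flat key=value configuration file
#'
#' Plain-text config with one `key = value` per line; `#` starts a comment.
#' Recognized keys are the arguments of [analysis_config] plus the
#' [feature_config] scalars (`min_sigma`, `max_sigma`, `membrane_thickness`,
#' `membrane_patch_size`) and `families` (comma-separated). Unknown keys are
#' an error, so typos never pass silently. Values given in `overrides` take
#' precedence over the file (the CLI routes its flags through this).
#'
#' @param path Config file path, or `NULL` for defaults only.
#' @param overrides Named list of values that beat the file.
#' @return An [analysis_config].
#' @export
read_config <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) stop("malformed config line: '", ln, "'")
      kv[[m[2]]] <- trimws(m[3])
    }
  }
  kv[names(overrides)] <- overrides
  build_config_from_kv(kv)
}

build_config_from_kv <- function(kv) {
  num <- function(k, d) if (is.null(kv[[k]])) d else as.numeric(kv[[k]])
  lgl <- function(k, d) if (is.null(kv[[k]])) d else
    tolower(as.character(kv[[k]])) %in% c("true", "1", "yes", "on")
  chr <- function(k, d) if (is.null(kv[[k]])) d else as.character(kv[[k]])
  known <- c("threshold", "min_size", "max_size", "watershed", "connectivity",
             "model_type", "seed", "families", "min_sigma", "max_sigma",
             "membrane_thickness", "membrane_patch_size")
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  model_type <- chr("model_type", "random_forest")
  fams <- kv[["families"]]
  fams <- if (is.null(fams)) default_families(model_type) else
    trimws(strsplit(as.character(fams), ",")[[1]])
  fc <- feature_config(min_sigma = num("min_sigma", 1),
                       max_sigma = num("max_sigma", 16),
                       membrane_thickness = num("membrane_thickness", 1),
                       membrane_patch_size = num("membrane_patch_size", 19),
                       families = fams)
  analysis_config(threshold = num("threshold", 0.5),
                  min_size = num("min_size", 50),
                  max_size = num("max_size", 1000),
                  watershed = lgl("watershed", FALSE),
                  connectivity = num("connectivity", 8),
                  model_type = model_type,
                  seed = num("seed", 1),
                  feature_config = fc)
}

#' @rdname read_config
#' @param config An [analysis_config] to serialize.
#' @export
write_config <- function(config, path) {
  fc <- config$feature_config
  lines <- c(
    sprintf("threshold = %.17g", config$threshold),
    sprintf("min_size = %d", config$min_size),
    sprintf("max_size = %d", config$max_size),
    sprintf("watershed = %s", tolower(config$watershed)),
    sprintf("connectivity = %d", config$connectivity),
    sprintf("model_type = %s", config$model_type),
    sprintf("seed = %d", config$seed),
    sprintf("min_sigma = %.17g", fc$min_sigma),
    sprintf("max_sigma = %.17g", fc$max_sigma),
    sprintf("membrane_thickness = %d", fc$membrane_thickness),
    sprintf("membrane_patch_size = %d", fc$membrane_patch_size),
    sprintf("families = %s", paste(fc$families, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a validation overlay image
#'
#' Renders the standard evaluation palette over the grayscale input: true
#' positive objects blue, false positive objects red, and unmatched (false
#' negative) marker positions as yellow disks.
#'
#' @param image The source [image_plane] (drawn as the grayscale background).
#' @param objects A [cell_objects] set as produced by the counting pipeline.
#' @param match The [match_markers] result for these objects and markers.
#' @param path Output PNG path.
#' @param marker_radius Radius of the yellow false-negative disks, px.
#' @return The path, invisibly.
#' @export
write_overlay <- function(image, objects, match, path, marker_radius = 4L) {
  image <- as_image_plane(image)
  g <- image$pixels
  rng <- range(g)
  g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  r <- g; b <- g; gg <- g
  lab <- objects$labels
  tally <- match$per_object
  tp_ids <- tally$object_id[tally$n_markers >= 1L]
  fp_ids <- tally$object_id[tally$n_markers == 0L]
  tp_px <- lab %in% tp_ids & lab > 0L
  fp_px <- lab %in% fp_ids & lab > 0L
  r[tp_px] <- 0;   gg[tp_px] <- 0;   b[tp_px] <- 1    # blue
  r[fp_px] <- 1;   gg[fp_px] <- 0;   b[fp_px] <- 0    # red
  fn <- match$unmatched_markers
  if (nrow(fn)) {
    for (i in seq_len(nrow(fn))) {
      rows <- (fn$y[i] + 1L) + seq(-marker_radius, marker_radius)
      cols <- (fn$x[i] + 1L) + seq(-marker_radius, marker_radius)
      rows <- rows[rows >= 1L & rows <= nrow(g)]
      cols <- cols[cols >= 1L & cols <= ncol(g)]
      dd <- outer((rows - fn$y[i] - 1L)^2, (cols - fn$x[i] - 1L)^2, `+`)
      sel <- dd <= marker_radius^2
      r[rows, cols][sel] <- 1; gg[rows, cols][sel] <- 1  # yellow
      b[rows, cols][sel] <- 0
    }
  }
  rgb <- array(c(r, gg, b), dim = c(nrow(g), ncol(g), 3L))
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write a results table to CSV
#'
#' CSV writer with a stable column order and full numeric precision, so that
#' numeric fields round-trip losslessly (well beyond 10 significant digits).
#'
#' @param records A data frame (or list of identically named lists).
#' @param path Output CSV path.
#' @param columns Optional character vector fixing the column order.
#' @export
write_results_table <- function(records, path, columns = NULL) {
  if (!is.data.frame(records)) {
    records <- if (length(records) == 0L) data.frame() else
      do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, names(records))
    if (length(missing_cols) && nrow(records))
      stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
    if (nrow(records)) records <- records[, columns, drop = FALSE]
    else records <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(columns))), columns)
  }
  utils::write.csv(format(records, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
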