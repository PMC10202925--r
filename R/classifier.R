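#' Assemble a pixel training set from annotation masks
#'
#' Extracts one training sample per labeled pixel across a set of paired
#' images and sparse annotation masks (1 = cell, 2 = background, 0 ignored).
#' Every mask must carry at least one pixel of each class, so a mislabelled
#' or empty mask is caught at assembly time with the offending image named.
#'
#' @param images List of [image_plane] objects (or matrices).
#' @param masks List of [annotation_mask] objects (or matrices in {0,1,2}),
#'   parallel to `images`.
#' @param config A [feature_config] describing the features to extract.
#' @return A `training_set`: list with `X` (feature matrix), `y` (factor with
#'   levels `cell`, `background`), `provenance` (data frame image_id/row/col)
#'   and `feature_config`.
#' @export
assemble_training_set <- function(images, masks, config = feature_config()) {
  if (length(images) != length(masks))
    stop("images and masks must be paired lists of equal length")
  if (length(images) == 0L) stop("no training images supplied")
  Xs <- list(); ys <- list(); prov <- list()
  for (i in seq_along(images)) {
    img <- as_image_plane(images[[i]])
    msk <- masks[[i]]
    id <- if (nzchar(img$image_id)) img$image_id else
      if (!is.null(attr(msk, "image_id")) && nzchar(attr(msk, "image_id")))
        attr(msk, "image_id") else paste0("image_", i)
    if (!all(dim(msk) == dim(img$pixels)))
      stop("mask/image shape mismatch for '", id, "'")
    if (!all(msk %in% c(0, 1, 2)))
      stop("mask labels outside {0,1,2} for '", id, "'")
    n_cell <- sum(msk == 1); n_bg <- sum(msk == 2)
    if (n_cell == 0L || n_bg == 0L)
      stop("annotation mask for '", id,
           "' must contain both cell (1) and background (2) pixels")
    stack <- build_feature_stack(img, config)
    sel <- which(msk != 0)
    Xi <- apply(stack, 3L, function(p) p[sel])
    if (length(sel) == 1L) Xi <- matrix(Xi, nrow = 1L,
                                        dimnames = list(NULL, dimnames(stack)[[3]]))
    Xs[[i]] <- Xi
    ys[[i]] <- ifelse(msk[sel] == 1, "cell", "background")
    rc <- arrayInd(sel, dim(msk))
    prov[[i]] <- data.frame(image_id = id, row = rc[, 1] - 1L,
                            col = rc[, 2] - 1L)
  }
  structure(list(X = do.call(rbind, Xs),
                 y = factor(unlist(ys), levels = c("cell", "background")),
                 provenance = do.call(rbind, prov),
                 feature_config = config),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d samples (%d cell / %d background), %d features, %d image(s)\n",
              length(x$y), sum(x$y == "cell"), sum(x$y == "background"),
              ncol(x$X), length(unique(x$provenance$image_id))))
  invisible(x)
}

merge_training_sets <- function(a, b) {
  stopifnot(identical(colnames(a$X), colnames(b$X)))
  structure(list(X = rbind(a$X, b$X),
                 y = factor(c(as.character(a$y), as.character(b$y)),
                            levels = c("cell", "background")),
                 provenance = rbind(a$provenance, b$provenance),
                 feature_config = a$feature_config),
            class = "training_set")
}

#' Train a probabilistic pixel classifier
#'
#' Fits the classifier that maps per-pixel feature vectors to the probability
#' of the `cell` class. Two flavors are available: a random forest (200
#' trees, sqrt(p) features per split, no depth cap) and a Gaussian naive
#' Bayes model. Training is bit-for-bit reproducible for a fixed seed.
#'
#' @param training_set A [assemble_training_set] result.
#' @param model_type `"random_forest"` or `"bayes"`.
#' @param seed Integer seed.
#' @param num_trees Number of trees for the forest flavor.
#' @param version_tag Label identifying this iteration within a lineage.
#' @return An object of class `pixel_classifier` with components `model_type`,
#'   `fit`, `feature_names`, `feature_config`, `training_seed`, `version_tag`,
#'   `n_samples` and `training_accuracy`.
#' @export
train_pixel_classifier <- function(training_set,
                                   model_type = c("random_forest", "bayes"),
                                   seed = 1L, num_trees = 200L,
                                   version_tag = "v001") {
  model_type <- match.arg(model_type)
  stopifnot(inherits(training_set, "training_set"))
  if (nlevels(droplevels(training_set$y)) < 2L)
    stop("training set must contain both classes")
  X <- training_set$X
  y <- training_set$y
  if (model_type == "random_forest") {
    df <- as.data.frame(X)
    df$.class <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".class", data = df,
      num.trees = num_trees, probability = TRUE,
      mtry = max(1L, floor(sqrt(ncol(X)))),
      seed = as.integer(seed), num.threads = 1L,
      respect.unordered.factors = "order")
  } else {
    # Gaussian naive Bayes; constant columns get a variance floor so they
    # carry no discriminative weight instead of producing NaN likelihoods
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    fit <- e1071::naiveBayes(x = as.data.frame(X), y = y)
    for (k in seq_along(fit$tables))
      fit$tables[[k]][, 2] <- pmax(fit$tables[[k]][, 2], 1e-6)
  }
  clf <- structure(list(model_type = model_type, fit = fit,
                        feature_names = colnames(X),
                        feature_config = training_set$feature_config,
                        training_seed = as.integer(seed),
                        num_trees = as.integer(num_trees),
                        version_tag = version_tag,
                        n_samples = nrow(X),
                        training_accuracy = NA_real_),
                   class = "pixel_classifier")
  p <- predict_feature_matrix(clf, X)
  clf$training_accuracy <-
    mean((p >= 0.5) == (y == "cell"))
  clf
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %s (%s), %d features, %d training pixels, training accuracy %.3f\n",
              x$version_tag, x$model_type, length(x$feature_names),
              x$n_samples, x$training_accuracy))
  invisible(x)
}

#' @export
summary.pixel_classifier <- function(object, ...) {
  print(object)
  cat("  feature families:",
      paste(object$feature_config$families, collapse = ", "), "\n")
  cat(sprintf("  seed %d%s\n", object$training_seed,
              if (object$model_type == "random_forest")
                sprintf(", %d trees", object$num_trees) else ""))
  invisible(object)
}

# Probability of class "cell" for a plain feature matrix.
predict_feature_matrix <- function(classifier, X) {
  missing_f <- setdiff(classifier$feature_names, colnames(X))
  if (length(missing_f))
    stop("feature mismatch; missing feature(s): ",
         paste(missing_f, collapse = ", "))
  X <- X[, classifier$feature_names, drop = FALSE]
  if (classifier$model_type == "random_forest") {
    pr <- predict(classifier$fit, as.data.frame(X),
                  num.threads = 1L)$predictions
    as.numeric(pr[, "cell"])
  } else {
    pr <- predict(classifier$fit, as.data.frame(X), type = "raw")
    as.numeric(pr[, "cell"])
  }
}

#' Predict a probability map
#'
#' Applies a trained pixel classifier to a feature stack, giving the
#' per-pixel probability that the pixel belongs to a cell.
#'
#' @param classifier A [train_pixel_classifier] result.
#' @param feature_stack A [build_feature_stack] result (its feature names
#'   must cover the classifier's).
#' @return A `probability_map`: numeric matrix in \[0, 1\] with the stack's
#'   spatial dimensions.
#' @export
predict_probability <- function(classifier, feature_stack) {
  d <- dim(feature_stack)
  X <- matrix(feature_stack, nrow = d[1] * d[2], ncol = d[3],
              dimnames = list(NULL, dimnames(feature_stack)[[3]]))
  p <- predict_feature_matrix(classifier, X)
  p <- pmin(pmax(p, 0), 1)
  structure(matrix(p, d[1], d[2]),
            class = c("probability_map", "matrix", "array"))
}

#' @export
predict.pixel_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_stack") ||
      (is.array(newdata) && length(dim(newdata)) == 3L))
    predict_probability(object, newdata)
  else predict_feature_matrix(object, as.matrix(newdata))
}

# ---- lineage ---------------------------------------------------------------

#' Classifier lineage: iteratively grown classifier versions
#'
#' The iterative training scheme adds a few labeled pixels at a time and
#' saves a classifier version after each addition; the lineage holds the
#' ordered versions together with the cumulative training set behind each,
#' so any iteration can be ranked, audited or re-applied later.
#'
#' @param training_set Initial [assemble_training_set] result.
#' @param model_type,seed,num_trees Passed to [train_pixel_classifier]; the
#'   same seed is reused for every version so versions differ only by data.
#' @return An object of class `classifier_lineage`: list with `versions`
#'   (list of `pixel_classifier`), `snapshots` (cumulative training sets),
#'   `model_type`, `seed`.
#' @export
new_lineage <- function(training_set, model_type = c("random_forest", "bayes"),
                        seed = 1L, num_trees = 200L) {
  model_type <- match.arg(model_type)
  clf <- train_pixel_classifier(training_set, model_type, seed = seed,
                                num_trees = num_trees, version_tag = "v001")
  structure(list(versions = list(clf), snapshots = list(training_set),
                 model_type = model_type, seed = as.integer(seed),
                 num_trees = as.integer(num_trees)),
            class = "classifier_lineage")
}

#' Extend a lineage with new annotations
#'
#' Appends one classifier version trained on the cumulative data (all prior
#' samples plus the new increment). Prior versions are untouched, and the
#' training sets behind successive versions are nested by construction.
#'
#' @param lineage A [new_lineage] result.
#' @param images,masks The new annotation increment (non-empty), as in
#'   [assemble_training_set].
#' @return The extended `classifier_lineage`.
#' @export
extend_lineage <- function(lineage, images, masks) {
  stopifnot(inherits(lineage, "classifier_lineage"))
  if (length(images) == 0L || length(masks) == 0L)
    stop("lineage increment must contain at least one annotated image")
  inc <- assemble_training_set(images, masks,
                               config = lineage$snapshots[[1]]$feature_config)
  cum <- merge_training_sets(lineage$snapshots[[length(lineage$snapshots)]], inc)
  tag <- sprintf("v%03d", length(lineage$versions) + 1L)
  clf <- train_pixel_classifier(cum, lineage$model_type, seed = lineage$seed,
                                num_trees = lineage$num_trees, version_tag = tag)
  lineage$versions <- c(lineage$versions, list(clf))
  lineage$snapshots <- c(lineage$snapshots, list(cum))
  lineage
}

#' @export
print.classifier_lineage <- function(x, ...) {
  cat(sprintf("<classifier_lineage> %d version(s), model %s, seed %d\n",
              length(x$versions), x$model_type, x$seed))
  for (v in x$versions)
    cat(sprintf("  %s: %d samples, training accuracy %.3f\n",
                v$version_tag, v$n_samples, v$training_accuracy))
  invisible(x)
}

#' @export
length.classifier_lineage <- function(x) length(x$versions)

#' Save or load a classifier as a single-file archive
#'
#' A classifier (model state, feature configuration, seed, version tag) is
#' stored as one file, so a counting study is reproducible by sharing the
#' model file and the image set.
#'
#' @param classifier A `pixel_classifier`.
#' @param path Archive path (conventionally `.rds`).
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "pixel_classifier"))
    stop("file does not contain a pixel_classifier: ", path)
  obj
}

#' @rdname save_classifier
#' @param lineage A `classifier_lineage`.
#' @param dir Directory receiving one archive per version (v001.rds, ...).
#' @export
save_lineage <- function(lineage, dir) {
  stopifnot(inherits(lineage, "classifier_lineage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in lineage$versions)
    save_classifier(v, file.path(dir, paste0(v$version_tag, ".rds")))
  saveRDS(lineage, file.path(dir, "lineage.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_lineage <- function(dir) {
  p <- file.path(dir, "lineage.rds")
  if (!file.exists(p)) stop("no lineage archive found in ", dir)
  obj <- readRDS(p)
  if (!inherits(obj, "classifier_lineage"))
    stop("not a classifier_lineage archive: ", p)
  obj
}

# Save/restore the global RNG state so seeded internals never disturb the
# caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
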