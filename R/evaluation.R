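#' Match manual markers against counted objects
#'
#' Cell-level bookkeeping: a marker lies inside an object when its rounded
#' pixel belongs to the object's pixel set. True positives are objects that
#' contain at least one marker; false positives are objects containing none;
#' false negatives are markers inside no object plus, for each object, every
#' marker beyond the first (insufficient object separation). Consequently
#' TP + FP = number of objects and TP + FN = number of markers, always.
#'
#' When a usable-area mask is supplied, objects whose centroid falls outside
#' the usable region and markers outside it are excluded before matching.
#'
#' @param objects A [label_objects]/[count_cells] object set.
#' @param markers A [marker_set] (columns `x`, `y`, 0-based).
#' @param usable Optional [usable_mask].
#' @param image_id Identifier carried into the result.
#' @return A `match_result`: list with `image_id`, `TP`, `FP`, `FN`,
#'   `n_objects`, `n_markers`, `per_object` (data frame `object_id`,
#'   `n_markers`) and `unmatched_markers` (data frame `x`, `y`).
#' @export
match_markers <- function(objects, markers, usable = NULL, image_id = NULL) {
  lab <- objects$labels
  tab <- objects$table
  mk <- as.data.frame(markers)[, c("x", "y"), drop = FALSE]
  if (is.null(image_id))
    image_id <- if (!is.null(attr(markers, "image_id")))
      attr(markers, "image_id") else ""
  if (!is.null(usable)) {
    stopifnot(all(dim(usable) == dim(lab)))
    if (nrow(tab)) {
      cx <- round_half_up(tab$centroid_x); cy <- round_half_up(tab$centroid_y)
      ok <- usable[cbind(cy + 1L, cx + 1L)]
      drop_ids <- tab$object_id[!ok]
      if (length(drop_ids)) lab[lab %in% drop_ids] <- 0L
      tab <- tab[ok, , drop = FALSE]
    }
    if (nrow(mk)) mk <- mk[usable[cbind(mk$y + 1L, mk$x + 1L)], , drop = FALSE]
  }
  if (nrow(mk) && (any(mk$x < 0) || any(mk$y < 0) ||
                   any(mk$x >= ncol(lab)) || any(mk$y >= nrow(lab))))
    stop("marker outside image bounds")
  hit <- if (nrow(mk)) lab[cbind(mk$y + 1L, mk$x + 1L)] else integer()
  n_obj <- nrow(tab)
  per_obj <- data.frame(object_id = tab$object_id,
                        n_markers = if (n_obj)
                          as.integer(tabulate(hit[hit > 0L],
                                              nbins = max(tab$object_id, 1L))[tab$object_id])
                        else integer())
  tp <- sum(per_obj$n_markers >= 1L)
  fp <- n_obj - tp
  fn_outside <- sum(hit == 0L)
  fn_excess <- sum(pmax(per_obj$n_markers - 1L, 0L))
  structure(list(image_id = image_id,
                 TP = as.integer(tp), FP = as.integer(fp),
                 FN = as.integer(fn_outside + fn_excess),
                 n_objects = as.integer(n_obj),
                 n_markers = as.integer(nrow(mk)),
                 per_object = per_obj,
                 unmatched_markers = mk[hit == 0L, , drop = FALSE]),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s: TP %d, FP %d, FN %d (%d objects, %d markers)\n",
              if (nzchar(x$image_id)) x$image_id else "(unnamed)",
              x$TP, x$FP, x$FN, x$n_objects, x$n_markers))
  invisible(x)
}

#' Detection metrics from a match result
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = their harmonic mean,
#' and accuracy = TP/(TP+FP+FN) — the cell-level accuracy that penalizes both
#' spurious and missed detections without needing true negatives. Metrics
#' with a zero denominator are reported as 0 with `degenerate = TRUE` so
#' rankings and tables never contain missing values.
#'
#' @param match A [match_markers] result, or an object with `TP`,`FP`,`FN`.
#' @param scope `"per_image"` or `"pooled"` label carried into the record.
#' @return A `metrics_record`: one-row data frame with columns `TP`, `FP`,
#'   `FN`, `precision`, `recall`, `f1`, `accuracy`, `degenerate`, `scope`.
#' @export
compute_metrics <- function(match, scope = "per_image") {
  tp <- match$TP; fp <- match$FP; fn <- match$FN
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  accuracy <- safe_div(tp, tp + fp + fn)
  degenerate <- any(is.na(c(precision, recall, f1, accuracy)))
  out <- data.frame(TP = tp, FP = fp, FN = fn,
                    precision = ifelse(is.na(precision), 0, precision),
                    recall = ifelse(is.na(recall), 0, recall),
                    f1 = ifelse(is.na(f1), 0, f1),
                    accuracy = ifelse(is.na(accuracy), 0, accuracy),
                    degenerate = degenerate, scope = scope)
  class(out) <- c("metrics_record", "data.frame")
  out
}

#' Pool match results across images
#'
#' The pooled statistics are computed from the summed TP/FP/FN over all
#' images ("calculated from total cells in the dataset"), while the spread of
#' the per-image statistics is reported as the standard error of the mean of
#' each metric across images.
#'
#' @param matches List of [match_markers] results (>= 1).
#' @return List with `pooled` (a [compute_metrics] record with scope
#'   `"pooled"`), `per_image` (data frame of per-image metrics) and `sem`
#'   (named numeric: SEM of precision, recall, f1, accuracy across images;
#'   0 for a single image).
#' @export
pool_metrics <- function(matches) {
  if (length(matches) == 0L) stop("pool_metrics needs at least one image")
  per <- do.call(rbind, lapply(matches, function(m) {
    r <- compute_metrics(m)
    r$image_id <- m$image_id
    r
  }))
  tot <- list(TP = sum(per$TP), FP = sum(per$FP), FN = sum(per$FN))
  pooled <- compute_metrics(tot, scope = "pooled")
  sem1 <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  sem <- vapply(per[c("precision", "recall", "f1", "accuracy")], sem1,
                numeric(1))
  list(pooled = pooled, per_image = per, sem = sem)
}

#' Mean absolute error between automatic and manual counts
#'
#' @param auto_counts,manual_counts Equal-length numeric vectors of per-image
#'   counts.
#' @return Mean of the absolute per-image count differences.
#' @export
mean_absolute_error <- function(auto_counts, manual_counts) {
  if (length(auto_counts) != length(manual_counts))
    stop("auto and manual count vectors must have equal length")
  mean(abs(auto_counts - manual_counts))
}

#' Rank classifier iterations on a validation set
#'
#' Runs every lineage version through the full counting pipeline on the
#' validation images, matches against the manual markers, and ranks versions
#' by pooled F1 score (ties broken by pooled precision, then version order).
#' Feature stacks are computed once per image and shared across versions.
#' When group labels are supplied, a per-version comparison of per-image
#' accuracy between groups is attached (Welch t-test for two groups, one-way
#' ANOVA for more).
#'
#' @param lineage A [new_lineage]/[extend_lineage] result.
#' @param images List of validation [image_plane] objects.
#' @param markers List of [marker_set] objects, parallel to `images`.
#' @param config An [analysis_config].
#' @param groups Optional factor/character vector of group labels per image.
#' @param usable Optional list of [usable_mask] objects (or `NULL` entries).
#' @return A `classifier_ranking`: data frame, one row per version in rank
#'   order, with pooled metrics, SEMs, MAE, and (if grouped) the group
#'   difference p-value; attribute `per_version` holds the match lists.
#' @export
rank_classifiers <- function(lineage, images, markers, config = analysis_config(),
                             groups = NULL, usable = NULL) {
  stopifnot(inherits(lineage, "classifier_lineage"))
  if (length(images) == 0L) stop("no validation images")
  if (length(markers) != length(images)) {
    ids <- vapply(seq_along(images), function(i)
      as_image_plane(images[[i]])$image_id, character(1))
    stop("missing markers for image(s): ",
         paste(ids[seq_along(images) > length(markers)], collapse = ", "))
  }
  missing_mk <- which(vapply(markers, is.null, logical(1)))
  if (length(missing_mk)) {
    ids <- vapply(missing_mk, function(i)
      as_image_plane(images[[i]])$image_id, character(1))
    stop("missing markers for image(s): ", paste(ids, collapse = ", "))
  }
  fc <- lineage$versions[[1]]$feature_config
  stacks <- lapply(images, build_feature_stack, config = fc)
  rows <- list(); per_version <- list()
  for (v in seq_along(lineage$versions)) {
    clf <- lineage$versions[[v]]
    matches <- vector("list", length(images))
    counts <- integer(length(images))
    for (i in seq_along(images)) {
      cc <- count_cells(images[[i]], clf, config, stack = stacks[[i]])
      matches[[i]] <- match_markers(cc$objects, markers[[i]],
                                    usable = if (is.null(usable)) NULL else usable[[i]],
                                    image_id = as_image_plane(images[[i]])$image_id)
      counts[i] <- cc$count
    }
    pm <- pool_metrics(matches)
    manual_n <- vapply(markers, nrow, integer(1))
    row <- data.frame(version_tag = clf$version_tag,
                      pm$pooled[, c("TP", "FP", "FN", "precision", "recall",
                                    "f1", "accuracy")],
                      sem_precision = pm$sem["precision"],
                      sem_recall = pm$sem["recall"],
                      sem_f1 = pm$sem["f1"],
                      sem_accuracy = pm$sem["accuracy"],
                      mae = mean_absolute_error(counts, manual_n))
    if (!is.null(groups)) {
      acc <- pm$per_image$accuracy
      g <- factor(groups)
      row$group_p <- if (nlevels(g) == 2L) {
        ttest_accuracy(acc[g == levels(g)[1]], acc[g == levels(g)[2]])$p_value
      } else {
        stats::anova(stats::lm(acc ~ g))$`Pr(>F)`[1]
      }
    }
    rows[[v]] <- row
    per_version[[clf$version_tag]] <- pm
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$f1, -out$precision, seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "per_version") <- per_version
  class(out) <- c("classifier_ranking", "data.frame")
  out
}

#' Object-level ROC curve over confidence thresholds
#'
#' Re-runs the full object pipeline (threshold, optional watershed, labeling,
#' size filter) and the marker matching at each confidence threshold,
#' recording the object-level rates. Without true negatives a classical
#' false-positive rate is undefined at the cell level, so the FP rate is
#' reported as FP/(TP+FP) (the complement of precision). Degenerate rows
#' (no objects or no markers) are emitted with a flag rather than dropped.
#'
#' @param classifier A trained [train_pixel_classifier].
#' @param images List of validation [image_plane] objects.
#' @param markers List of parallel [marker_set] objects.
#' @param thresholds Increasing vector in \[0, 1\]; default 0.05..0.95 by 0.05.
#' @param config An [analysis_config] (its `threshold` is ignored in favour
#'   of the sweep).
#' @return A `roc_curve`: data frame with columns `threshold`, `tp_rate`
#'   (= recall), `fp_rate` (= FP/(TP+FP)), `precision`, `recall`, `f1`,
#'   `accuracy`, `degenerate`.
#' @export
roc_curve <- function(classifier, images, markers,
                      thresholds = seq(0.05, 0.95, by = 0.05),
                      config = analysis_config()) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (any(thresholds < 0 | thresholds > 1)) stop("thresholds must lie in [0, 1]")
  stacks <- lapply(images, build_feature_stack,
                   config = classifier$feature_config)
  pmaps <- lapply(stacks, function(s) predict_probability(classifier, s))
  rows <- lapply(thresholds, function(th) {
    matches <- lapply(seq_along(images), function(i) {
      mask <- binarize(pmaps[[i]], th)
      if (config$watershed) mask <- separate_touching(mask)
      obj <- filter_by_size(label_objects(mask, config$connectivity),
                            config$min_size, config$max_size)
      match_markers(obj, markers[[i]],
                    image_id = as_image_plane(images[[i]])$image_id)
    })
    pooled <- pool_metrics(matches)$pooled
    data.frame(threshold = th,
               tp_rate = pooled$recall,
               fp_rate = if (pooled$TP + pooled$FP > 0)
                 pooled$FP / (pooled$TP + pooled$FP) else 0,
               precision = pooled$precision, recall = pooled$recall,
               f1 = pooled$f1, accuracy = pooled$accuracy,
               degenerate = pooled$degenerate)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$threshold, x$tp_rate, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = "confidence threshold", ylab = "rate",
                 main = "Object-level rates over confidence thresholds", ...)
  graphics::lines(x$threshold, x$fp_rate, type = "b", pch = 1, lty = 2)
  graphics::lines(x$threshold, x$precision, type = "b", pch = 2, lty = 3)
  graphics::legend("left", legend = c("TP rate (recall)", "FP rate (1 - precision)",
                                      "precision"),
                   pch = c(16, 1, 2), lty = c(1, 2, 3), bty = "n")
  invisible(x)
}

#' Audit a selected classifier on held-out images
#'
#' Re-runs the validation computation on a marker-annotated audit set drawn
#' from the experimental data, and reports the metric deltas against the
#' validation-stage metrics, answering how similarly the classifier performs
#' beyond the images it was selected on. Audit images must be disjoint from
#' the training and validation sets by image id (override with
#' `allow_overlap` for the deliberate audit-equals-validation check).
#'
#' @param classifier The selected [train_pixel_classifier].
#' @param images List of audit [image_plane] objects (non-empty).
#' @param markers List of parallel [marker_set] objects.
#' @param config An [analysis_config].
#' @param validation_metrics Optional pooled [compute_metrics] record from
#'   the validation stage; enables the delta report.
#' @param reserved_ids Character vector of training/validation image ids.
#' @param allow_overlap Permit audit ids inside `reserved_ids`.
#' @param usable Optional list of [usable_mask] objects.
#' @return List with `pooled`, `per_image`, `sem` (as [pool_metrics]) and
#'   `delta` (audit minus validation for precision/recall/f1/accuracy, or
#'   `NULL`).
#' @export
audit_classifier <- function(classifier, images, markers,
                             config = analysis_config(),
                             validation_metrics = NULL,
                             reserved_ids = character(),
                             allow_overlap = FALSE, usable = NULL) {
  if (length(images) == 0L) stop("audit set is empty")
  ids <- vapply(images, function(im) as_image_plane(im)$image_id, character(1))
  overlap <- intersect(ids, reserved_ids)
  if (length(overlap) && !allow_overlap)
    stop("audit images overlap training/validation set: ",
         paste(overlap, collapse = ", "))
  matches <- lapply(seq_along(images), function(i) {
    cc <- count_cells(images[[i]], classifier, config)
    match_markers(cc$objects, markers[[i]],
                  usable = if (is.null(usable)) NULL else usable[[i]],
                  image_id = ids[i])
  })
  pm <- pool_metrics(matches)
  delta <- NULL
  if (!is.null(validation_metrics)) {
    cols <- c("precision", "recall", "f1", "accuracy")
    delta <- unlist(pm$pooled[cols]) - unlist(validation_metrics[cols])
  }
  c(pm, list(delta = delta))
}
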