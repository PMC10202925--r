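#' Area-normalized cell density
#'
#' Normalizes a per-image cell count to the usable image area, for images
#' where part of the field is unsuitable for detection (tissue damage,
#' thickness irregularity). Density is reported per pixel^2 and, when the
#' physical pixel size is known, additionally per mm^2.
#'
#' @param count Non-negative cell count.
#' @param usable Either a [usable_mask], a logical matrix, or a single
#'   number of usable pixels (e.g. `height * width` for a fully usable
#'   image).
#' @param pixel_size Optional pixel side length in micrometres.
#' @param image_id,group,method Labels carried into the record.
#' @return A `density_record`: one-row data frame with columns `image_id`,
#'   `group`, `method`, `count`, `usable_area_px`, `density_per_px2` and
#'   (when `pixel_size` is given) `usable_area_mm2`, `density_per_mm2`.
#' @export
cell_density <- function(count, usable, pixel_size = NULL, image_id = "",
                         group = "", method = "") {
  if (count < 0) stop("count must be non-negative")
  area_px <- if (is.matrix(usable)) sum(usable != 0) else as.numeric(usable)
  if (!is.finite(area_px) || area_px <= 0) stop("usable area must be positive")
  out <- data.frame(image_id = image_id, group = group, method = method,
                    count = count, usable_area_px = area_px,
                    density_per_px2 = count / area_px)
  if (!is.null(pixel_size)) {
    px_per_mm2 <- (1000 / pixel_size)^2
    out$usable_area_mm2 <- area_px / px_per_mm2
    out$density_per_mm2 <- out$density_per_px2 * px_per_mm2
  }
  class(out) <- c("density_record", "data.frame")
  out
}

#' Two-way ANOVA with Tukey HSD on cell density
#'
#' Tests the experimental-group effect, the counting-method effect, and
#' their interaction on per-image density, using type-II sums of squares
#' (robust to the unbalanced group sizes typical of imaging studies),
#' followed by Tukey HSD post-hoc comparisons across counting methods.
#'
#' @param records Data frame of stacked [cell_density] records (or any data
#'   frame with columns `density`, `group`, `method`; density defaults to
#'   `density_per_px2` when `density` is absent).
#' @return A `group_comparison`: list with `anova` (data frame with one row
#'   per effect: `effect`, `F`, `p`), `tukey` (data frame of pairwise method
#'   contrasts: `contrast`, `diff`, `lwr`, `upr`, `p_adj`) and `model` (the
#'   underlying `lm`).
#' @export
two_way_anova_tukey <- function(records) {
  df <- as.data.frame(records)
  if (!"density" %in% names(df)) {
    if (!"density_per_px2" %in% names(df))
      stop("records need a 'density' (or 'density_per_px2') column")
    df$density <- df$density_per_px2
  }
  df$group <- factor(df$group)
  df$method <- factor(df$method)
  if (nlevels(df$group) < 2L || nlevels(df$method) < 2L)
    stop("need >= 2 groups and >= 2 methods")
  cells <- table(df$group, df$method)
  empty <- which(cells < 2L, arr.ind = TRUE)
  if (nrow(empty))
    stop("design cell(s) with fewer than 2 replicates: ",
         paste(sprintf("%s:%s", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "))
  fit <- stats::lm(density ~ group * method, data = df)
  a2 <- car::Anova(fit, type = 2)
  eff <- rownames(a2)
  keep <- eff != "Residuals"
  anova_tab <- data.frame(effect = eff[keep],
                          F = a2[keep, "F value"],
                          p = a2[keep, "Pr(>F)"])
  aovfit <- stats::aov(density ~ group * method, data = df)
  tk <- stats::TukeyHSD(aovfit, which = "method")$method
  tukey_tab <- data.frame(contrast = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL)
  structure(list(anova = anova_tab, tukey = tukey_tab, model = fit),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> type-II two-way ANOVA on density\n")
  print(x$anova, row.names = FALSE)
  cat("Tukey HSD across methods:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Two-sample t-test of per-image accuracy between groups
#'
#' Compares per-image accuracy (or any per-image statistic) between two
#' experimental groups. Defaults to the Welch unequal-variance form;
#' `var_equal = TRUE` gives the classical pooled-variance test.
#'
#' @param groupA_values,groupB_values Numeric vectors, each of length >= 2.
#' @param var_equal Use the pooled-variance (classical) form.
#' @return List with `t`, `df`, `p_value`, `mean_A`, `mean_B`.
#' @export
ttest_accuracy <- function(groupA_values, groupB_values, var_equal = FALSE) {
  if (length(groupA_values) < 2L || length(groupB_values) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(groupA_values) == 0 && stats::sd(groupB_values) == 0) {
    # both groups constant (e.g. a classifier with perfect per-image
    # accuracy): the test degenerates; report it rather than fail
    same <- mean(groupA_values) == mean(groupB_values)
    return(list(t = if (same) 0 else sign(mean(groupA_values) -
                                            mean(groupB_values)) * Inf,
                df = NA_real_, p_value = if (same) 1 else 0,
                mean_A = mean(groupA_values), mean_B = mean(groupB_values)))
  }
  ht <- stats::t.test(groupA_values, groupB_values, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_A = mean(groupA_values), mean_B = mean(groupB_values))
}

#' Regression of automatic against manual counts
#'
#' Ordinary least squares of the automatic count on the manual count,
#' summarizing how well the classifier tracks the observer image by image.
#' Reports slope, intercept, adjusted R^2 and the regression F-test p-value.
#'
#' @param auto_counts,manual_counts Paired numeric vectors, n >= 3.
#' @return A `regression_result`: list with `slope`, `intercept`,
#'   `adj_r_squared`, `p_value`, `n` and `model`.
#' @export
regress_counts <- function(auto_counts, manual_counts) {
  if (length(auto_counts) != length(manual_counts))
    stop("paired count vectors must have equal length")
  n <- length(auto_counts)
  if (n < 3L) stop("regression needs at least 3 paired counts")
  if (stats::var(manual_counts) == 0)
    stop("manual counts are constant; regression undefined")
  fit <- stats::lm(auto_counts ~ manual_counts)
  sm <- suppressWarnings(summary(fit))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((auto_counts - mean(auto_counts))^2)
  if (rss <= 1e-12 * max(tss, 1)) {
    adj_r2 <- 1
    p <- 0
  } else {
    adj_r2 <- sm$adj.r.squared
    f <- sm$fstatistic
    p <- stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 adj_r_squared = adj_r2, p_value = unname(p), n = n,
                 model = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> auto = %.4g + %.4g * manual (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  adjusted R^2 = %.4f, p = %.3g\n", x$adj_r_squared, x$p_value))
  invisible(x)
}
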