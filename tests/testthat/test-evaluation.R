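test_that("marker matching follows the cell-level TP/FP/FN rules", {
  empty <- objects_from_labels(matrix(0L, 10, 10))
  m0 <- match_markers(empty, marker_set(image_shape = c(10, 10)))
  expect_equal(c(m0$TP, m0$FP, m0$FN), c(0L, 0L, 0L))

  lab <- matrix(0L, 10, 10); lab[3:6, 3:6] <- 1L
  one <- objects_from_labels(lab)
  m2 <- match_markers(one, marker_set(c(3, 4), c(3, 4), image_shape = c(10, 10)))
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1L, 0L, 1L))  # second marker in excess

  lab3 <- matrix(0L, 12, 12)
  lab3[1:2, 1:2] <- 1L; lab3[5:6, 5:6] <- 2L; lab3[9:10, 9:10] <- 3L
  three <- objects_from_labels(lab3)
  m3 <- match_markers(three, marker_set(1, 1, image_shape = c(12, 12)))
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(1L, 2L, 0L))
})

test_that("matching agrees with the brute-force containment oracle", {
  set.seed(41)
  for (rep in 1:100) {
    sc <- random_object_scene(sample(0:12, 1), sample(0:15, 1))
    obj <- objects_from_labels(sc$labels)
    m <- match_markers(obj, sc$markers)
    o <- oracle_match(sc$labels, sc$markers)
    expect_identical(c(m$TP, m$FP, m$FN),
                     as.integer(c(o$TP, o$FP, o$FN)))
    # conservation
    expect_identical(m$TP + m$FP, m$n_objects)
    expect_identical(m$TP + m$FN, m$n_markers)
  }
})

test_that("usable-area masks exclude outside objects and markers before matching", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2:3] <- 1L          # centroid inside usable half
  lab[2:3, 8:9] <- 2L          # centroid outside
  um <- matrix(FALSE, 10, 10); um[, 1:5] <- TRUE
  mk <- marker_set(c(2, 8, 8), c(2, 2, 8), image_shape = c(10, 10))
  m <- match_markers(objects_from_labels(lab), mk, usable = um)
  expect_equal(m$n_objects, 1L)
  expect_equal(m$n_markers, 1L)
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 0L, 0L))
})

test_that("metric formulas and degenerate handling are exact", {
  r <- compute_metrics(make_match(6L, 2L, 2L))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.75)
  expect_equal(r$f1, 0.75)
  expect_equal(r$accuracy, 0.6)
  expect_false(r$degenerate)

  z <- compute_metrics(make_match(0L, 0L, 0L))
  expect_true(z$degenerate)
  expect_equal(unlist(z[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 0, recall = 0, f1 = 0, accuracy = 0))

  p <- compute_metrics(make_match(1L, 0L, 0L))
  expect_equal(unlist(p[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))
})

test_that("accuracy is bounded by precision, recall and F1 on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    r <- compute_metrics(make_match(tp, fp, fn))
    if (!r$degenerate) {
      expect_lte(r$accuracy, r$precision + 1e-12)
      expect_lte(r$accuracy, r$recall + 1e-12)
      expect_lte(r$accuracy, r$f1 + 1e-12)
    }
  }
})

test_that("pooling sums counts and reports per-image SEMs", {
  a <- make_match(5L, 0L, 5L); a$image_id <- "a"
  b <- make_match(5L, 5L, 0L); b$image_id <- "b"
  pm <- pool_metrics(list(a, b))
  expect_equal(pm$pooled$precision, 2 / 3)
  expect_equal(pm$pooled$recall, 2 / 3)
  expect_equal(pm$pooled$accuracy, 0.5)
  # precision and recall differ between the two images; f1 and accuracy
  # happen to coincide (0.667 / 0.5 on both), so their SEMs are exactly 0
  expect_true(all(pm$sem[c("precision", "recall")] > 0))
  expect_equal(unname(pm$sem[c("f1", "accuracy")]), c(0, 0))

  single <- pool_metrics(list(a))
  expect_equal(unname(single$sem), rep(0, 4))
  same <- pool_metrics(list(a, a))
  expect_equal(unname(same$sem), rep(0, 4))
  expect_equal(same$pooled$precision, compute_metrics(a)$precision)
  expect_error(pool_metrics(list()), "at least one")
})

test_that("mean absolute error matches its formula", {
  expect_equal(mean_absolute_error(c(10, 10), c(10, 10)), 0)
  expect_equal(mean_absolute_error(c(8, 12), c(10, 10)), 2)
  set.seed(43)
  a <- sample(0:50, 20); b <- sample(0:50, 20)
  expect_equal(mean_absolute_error(a, b), sum(abs(a - b)) / 20)
  expect_error(mean_absolute_error(1:3, 1:4), "equal length")
})

test_that("classifier ranking orders versions by pooled F1 and is deterministic", {
  sc_tr <- generate_scene(small_spec(seed = 51L), "rk_tr")
  # deliberately mistrained first version: the 3 px halo around every cell is
  # labeled "cell", so v001 dilates and merges objects; the v002 increment
  # adds correct tight-boundary labels, emulating retraining on areas of
  # incorrect segmentation
  set.seed(52)
  tl <- sc_tr$truth_labels > 0L
  halo <- as.matrix(EBImage::dilate(tl * 1, matrix(1, 7, 7))) > 0
  far <- as.matrix(EBImage::dilate(tl * 1, matrix(1, 17, 17))) == 0
  ann_bad <- matrix(0L, nrow(tl), ncol(tl))
  ann_bad[sample(which(halo), 200)] <- 1L
  ann_bad[sample(which(far), 200)] <- 2L
  ts <- assemble_training_set(list(sc_tr$image), list(ann_bad),
                              small_feature_config())
  lin <- new_lineage(ts, "random_forest", seed = 6L)
  lin <- extend_lineage(lin, list(sc_tr$image),
                        list(scene_annotation(sc_tr, 400, 400, seed = 53L)))
  val <- lapply(1:4, function(i) generate_scene(small_spec(seed = 60L + i),
                                                paste0("rk_val", i)))
  imgs <- lapply(val, `[[`, "image")
  mks <- lapply(val, `[[`, "markers")
  cfg <- small_config()
  rk <- rank_classifiers(lin, imgs, mks, cfg)
  expect_s3_class(rk, "classifier_ranking")
  expect_equal(nrow(rk), 2L)
  expect_true(all(diff(rk$f1) <= 0))
  expect_equal(rk$rank, 1:2)
  rk2 <- rank_classifiers(lin, imgs, mks, cfg)
  expect_identical(as.data.frame(rk), as.data.frame(rk2))
  # the richer version must not rank below the 15-pixel one
  expect_identical(rk$version_tag[1], "v002")
  expect_error(rank_classifiers(lin, imgs, mks[1:2], cfg), "missing markers")
})

test_that("single-version lineages rank trivially with group test attached", {
  sc_tr <- generate_scene(small_spec(seed = 55L), "rg_tr")
  ts <- assemble_training_set(list(sc_tr$image),
                              list(scene_annotation(sc_tr, 200, 200, seed = 56L)),
                              small_feature_config())
  lin <- new_lineage(ts, "random_forest", seed = 6L)
  val <- lapply(1:4, function(i) generate_scene(small_spec(seed = 70L + i),
                                                paste0("rg_val", i)))
  rk <- rank_classifiers(lin, lapply(val, `[[`, "image"),
                         lapply(val, `[[`, "markers"), small_config(),
                         groups = c("A", "A", "B", "B"))
  expect_equal(nrow(rk), 1L)
  expect_true(rk$group_p >= 0 && rk$group_p <= 1)
})

test_that("the ROC sweep emits monotone pixel behavior and flagged degenerate rows", {
  clf <- toy_classifier()
  sc <- generate_scene(small_spec(seed = 57L), "roc")
  cfg <- small_config()
  roc <- roc_curve(clf, list(sc$image), list(sc$markers),
                   thresholds = seq(0.1, 0.9, by = 0.1), config = cfg)
  expect_equal(nrow(roc), 9L)
  expect_true(all(roc$fp_rate >= 0 & roc$fp_rate <= 1))
  expect_true(all(abs(roc$fp_rate - (1 - roc$precision)) < 1e-12))
  # threshold 1.0 on a map that never reaches 1 -> degenerate row
  pmax_ <- max(predict_probability(clf, build_feature_stack(sc$image,
                                                            clf$feature_config)))
  if (pmax_ < 1) {
    roc1 <- roc_curve(clf, list(sc$image), list(sc$markers),
                      thresholds = 1.0, config = cfg)
    expect_true(roc1$degenerate)
    expect_equal(roc1$tp_rate, 0)
  }
  expect_error(roc_curve(clf, list(sc$image), list(sc$markers),
                         thresholds = c(0.5, 0.2), config = cfg),
               "increasing")
})

test_that("audit reproduces validation metrics on the same images and guards ids", {
  clf <- toy_classifier()
  cfg <- small_config()
  val <- lapply(1:3, function(i) generate_scene(small_spec(seed = 80L + i),
                                                paste0("aud", i)))
  imgs <- lapply(val, `[[`, "image")
  mks <- lapply(val, `[[`, "markers")
  base <- pool_metrics(lapply(1:3, function(i) {
    cc <- count_cells(imgs[[i]], clf, cfg)
    match_markers(cc$objects, mks[[i]], image_id = imgs[[i]]$image_id)
  }))
  res <- audit_classifier(clf, imgs, mks, cfg,
                          validation_metrics = base$pooled,
                          reserved_ids = c("aud1", "aud2", "aud3"),
                          allow_overlap = TRUE)
  expect_equal(unname(res$delta), rep(0, 4))
  expect_error(audit_classifier(clf, imgs, mks, cfg,
                                reserved_ids = "aud2"), "overlap")
  expect_error(audit_classifier(clf, list(), list(), cfg), "empty")
})
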