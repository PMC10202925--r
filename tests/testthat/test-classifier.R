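test_that("training sets are assembled one sample per labeled pixel", {
  img <- image_plane(matrix(runif(24 * 24, 0, 255), 24, 24), bit_depth = 8L,
                     image_id = "a")
  m <- matrix(0L, 24, 24)
  m[2, 2:6] <- 1L    # 5 cell pixels
  m[20, 2:6] <- 2L   # 5 background pixels
  fc <- feature_config(max_sigma = 2, families = c("gaussian", "dog"))
  ts <- assemble_training_set(list(img), list(m), fc)
  expect_equal(length(ts$y), 10L)
  expect_equal(sum(ts$y == "cell"), 5L)
  expect_identical(colnames(ts$X), feature_names(fc))

  img2 <- image_plane(matrix(runif(24 * 24, 0, 255), 24, 24), bit_depth = 8L,
                      image_id = "b")
  m2 <- matrix(0L, 24, 24); m2[5, 5] <- 1L; m2[9, 9:10] <- 2L
  ts2 <- assemble_training_set(list(img, img2), list(m, m2), fc)
  expect_equal(length(ts2$y), 13L)  # sum over disjoint labels

  expect_error(assemble_training_set(list(img), list(matrix(0L, 24, 24)), fc),
               "both cell")
  expect_error(assemble_training_set(list(img), list(matrix(0L, 5, 5)), fc),
               "shape mismatch")
})

test_that("the separable toy problem trains to accuracy 1 and is deterministic", {
  ts <- separable_training_set()
  for (mt in c("random_forest", "bayes")) {
    clf <- train_pixel_classifier(ts, mt, seed = 5L)
    expect_equal(clf$training_accuracy, 1.0)
    probe <- matrix(seq(0, 1, length.out = 21), ncol = 1,
                    dimnames = list(NULL, "f1"))
    p1 <- predict(clf, probe)
    p2 <- predict(train_pixel_classifier(ts, mt, seed = 5L), probe)
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
    expect_gt(p1[21], 0.5)   # cell-like feature
    expect_lt(p1[1], 0.5)    # background-like feature
  }
})

test_that("held-out accuracy on overlapping Gaussians approaches the Bayes rate", {
  # two classes N(0.4, 0.1) / N(0.6, 0.1), equal priors: the optimal rule
  # thresholds at 0.5 and errs at pnorm(-1) per class
  bayes_acc <- 1 - pnorm(-0.1 / 0.1)
  set.seed(31)
  n <- 2000L
  draw <- function(n) {
    x <- c(rnorm(n / 2, 0.4, 0.1), rnorm(n / 2, 0.6, 0.1))
    y <- factor(rep(c("cell", "background"), each = n / 2),
                levels = c("cell", "background"))
    # cell class is the LOW mode here; direction is irrelevant to accuracy
    list(X = matrix(x, ncol = 1, dimnames = list(NULL, "f1")), y = y)
  }
  tr <- draw(n); te <- draw(n)
  ts <- structure(list(X = tr$X, y = tr$y,
                       provenance = data.frame(image_id = "sim",
                                               row = seq_len(n), col = 0L),
                       feature_config = feature_config(max_sigma = 1,
                                                       families = "gaussian")),
                  class = "training_set")
  # the Gaussian naive-Bayes flavor is model-correct here and sits within 3
  # points of the bound; bagged deep trees give a few points more away near
  # the 1-D decision boundary, so the forest gets a wider band
  tol <- c(random_forest = 0.06, bayes = 0.03)
  for (mt in c("random_forest", "bayes")) {
    clf <- train_pixel_classifier(ts, mt, seed = 8L)
    acc <- mean((predict(clf, te$X) >= 0.5) == (te$y == "cell"))
    expect_gt(acc, bayes_acc - tol[[mt]])
    expect_lt(acc, bayes_acc + tol[[mt]])
  }
})

test_that("lineages grow by one nested version per increment", {
  sc <- generate_scene(small_spec(seed = 9L), "inc")
  ann <- scene_annotation(sc, 40, 40, seed = 10L)
  ts1 <- assemble_training_set(list(sc$image), list(ann), small_feature_config())
  lin1 <- new_lineage(ts1, "random_forest", seed = 2L)
  lin2 <- extend_lineage(lin1, list(sc$image),
                         list(scene_annotation(sc, 40, 40, seed = 11L)))
  expect_length(lin2, 2L)
  expect_identical(lin2$versions[[1]]$fit$forest,
                   lin1$versions[[1]]$fit$forest)  # prior version untouched
  expect_gte(lin2$versions[[2]]$n_samples, lin2$versions[[1]]$n_samples)
  expect_identical(lin2$versions[[2]]$version_tag, "v002")
  expect_error(extend_lineage(lin2, list(), list()), "at least one")
})

test_that("every version of a lineage on the separable toy keeps accuracy 1", {
  lin <- new_lineage(separable_training_set(40L, seed = 3L), seed = 4L)
  # grow with more separable data, twice
  for (k in 1:2) {
    inc <- separable_training_set(20L, seed = 10L + k)
    snap <- lin$snapshots[[length(lin$snapshots)]]
    merged <- segcount:::merge_training_sets(snap, inc)
    clf <- train_pixel_classifier(merged, lin$model_type, seed = lin$seed,
                                  version_tag = sprintf("v%03d", k + 1L))
    lin$versions <- c(lin$versions, list(clf))
    lin$snapshots <- c(lin$snapshots, list(merged))
  }
  for (v in lin$versions) expect_equal(v$training_accuracy, 1.0)
})

test_that("probability maps respect shape, range, and feature-name checks", {
  clf <- toy_classifier()
  sc <- generate_scene(small_spec(seed = 17L), "probe")
  st <- build_feature_stack(sc$image, clf$feature_config)
  pm <- predict_probability(clf, st)
  expect_equal(dim(pm), dim(sc$image$pixels))
  expect_true(all(pm >= 0 & pm <= 1))
  # background-only image stays below threshold everywhere
  bg <- generate_scene(small_spec(seed = 18L, n_cells = 0L), "bg")
  pm_bg <- predict_probability(clf, build_feature_stack(bg$image,
                                                        clf$feature_config))
  expect_true(all(pm_bg <= 0.5))
  wrong <- st[, , 1:3]
  expect_error(predict_probability(clf, wrong), "missing feature")
})

test_that("classifiers and lineages round-trip through their archives", {
  clf <- toy_classifier()
  p <- file.path(tempdir(), "clf.rds")
  save_classifier(clf, p)
  back <- load_classifier(p)
  expect_identical(back$feature_names, clf$feature_names)
  probe <- matrix(runif(30), 10, 3)
  sc <- generate_scene(small_spec(seed = 19L), "rt")
  st <- build_feature_stack(sc$image, clf$feature_config)
  expect_identical(predict_probability(back, st), predict_probability(clf, st))
  saveRDS(1:3, p)
  expect_error(load_classifier(p), "pixel_classifier")
})
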