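# Shared fixtures built once per test run. The trained classifiers are cached
# because forest training is the slowest step in the suite.

.fixture_cache <- new.env(parent = emptyenv())

# small scene spec used across tests: 96x96, well-separated cells
small_spec <- function(seed = 1L, n_cells = 12L, ...) {
  synthetic_spec(width = 96L, height = 96L, n_cells = n_cells,
                 radius_range = c(4, 6), seed = seed, ...)
}

small_feature_config <- function() feature_config(max_sigma = 4)

small_config <- function(...) {
  analysis_config(min_size = 20, max_size = 500,
                  feature_config = small_feature_config(), ...)
}

# classifier trained on one small scene; shared read-only
toy_classifier <- function() {
  if (is.null(.fixture_cache$toy_clf)) {
    sc <- generate_scene(small_spec(seed = 42L), "toy_train")
    ann <- scene_annotation(sc, 250, 250, seed = 43L)
    ts <- assemble_training_set(list(sc$image), list(ann),
                                config = small_feature_config())
    .fixture_cache$toy_clf <- train_pixel_classifier(ts, "random_forest",
                                                     seed = 7L)
  }
  .fixture_cache$toy_clf
}

# 1-feature linearly separable training set (cell >= 0.8, background <= 0.2)
separable_training_set <- function(n_per_class = 50L, seed = 1L) {
  set.seed(seed)
  X <- matrix(c(runif(n_per_class, 0.8, 1.0), runif(n_per_class, 0.0, 0.2)),
              ncol = 1, dimnames = list(NULL, "f1"))
  structure(list(X = X,
                 y = factor(rep(c("cell", "background"), each = n_per_class),
                            levels = c("cell", "background")),
                 provenance = data.frame(image_id = "toy",
                                         row = seq_len(2 * n_per_class),
                                         col = 0L),
                 feature_config = feature_config(max_sigma = 1,
                                                 families = "gaussian")),
            class = "training_set")
}

make_match <- function(tp, fp, fn) list(TP = tp, FP = fp, FN = fn)
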