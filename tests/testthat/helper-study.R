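# End-to-end study fixtures shared between the heavier tests: a 3-increment
# lineage trained on three 256x256 scenes of 50 separable cells, validated on
# 10 scenes of the same regime, at the default analysis configuration
# (threshold 0.5, size window 50..1000, default feature families).

recovery_spec <- function(seed) {
  synthetic_spec(width = 256L, height = 256L, n_cells = 50L,
                 radius_range = c(5, 8), seed = seed)
}

recovery_study <- function() {
  if (!is.null(.fixture_cache$recovery)) return(.fixture_cache$recovery)
  cfg <- analysis_config()
  train_scenes <- lapply(1:3, function(i)
    generate_scene(recovery_spec(100L + i), sprintf("train%02d", i)))
  anns <- lapply(seq_along(train_scenes), function(i)
    scene_annotation(train_scenes[[i]], 300, 300, seed = 200L + i))
  ts <- assemble_training_set(list(train_scenes[[1]]$image), list(anns[[1]]),
                              cfg$feature_config)
  lineage <- new_lineage(ts, cfg$model_type, seed = cfg$seed)
  for (i in 2:3)
    lineage <- extend_lineage(lineage, list(train_scenes[[i]]$image),
                              list(anns[[i]]))
  val_scenes <- lapply(1:10, function(i)
    generate_scene(recovery_spec(300L + i), sprintf("val%02d", i)))
  ranking <- rank_classifiers(lineage,
                              lapply(val_scenes, `[[`, "image"),
                              lapply(val_scenes, `[[`, "markers"),
                              cfg)
  top_tag <- ranking$version_tag[1]
  top <- Filter(function(v) v$version_tag == top_tag, lineage$versions)[[1]]
  counts <- vapply(val_scenes, function(s)
    count_cells(s$image, top, cfg)$count, numeric(1))
  truth <- vapply(val_scenes, function(s) nrow(s$truth), numeric(1))
  .fixture_cache$recovery <- list(config = cfg, lineage = lineage,
                                  ranking = ranking, classifier = top,
                                  val_counts = counts, val_truth = truth)
  .fixture_cache$recovery
}

# classifier + config for the group-effect study: 128x128 scenes, a reduced
# feature set (gaussian/sobel/hessian/dog) that keeps the 800-image sweep fast
group_study_config <- function() {
  analysis_config(min_size = 20, max_size = 500,
                  feature_config = feature_config(
                    families = c("gaussian", "sobel", "hessian", "dog")))
}

group_study_classifier <- function() {
  if (!is.null(.fixture_cache$group_clf)) return(.fixture_cache$group_clf)
  cfg <- group_study_config()
  scenes <- lapply(1:2, function(i)
    generate_scene(synthetic_spec(width = 128L, height = 128L, n_cells = 10L,
                                  radius_range = c(4, 6), seed = 400L + i),
                   sprintf("gtrain%d", i)))
  anns <- lapply(seq_along(scenes), function(i)
    scene_annotation(scenes[[i]], 250, 250, seed = 500L + i))
  ts <- assemble_training_set(lapply(scenes, `[[`, "image"), anns,
                              cfg$feature_config)
  .fixture_cache$group_clf <- train_pixel_classifier(ts, seed = 21L)
  .fixture_cache$group_clf
}
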