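test_that("scene generation is deterministic and respects the requested bounds", {
  spec <- small_spec(seed = 91L, n_cells = 8L)
  s1 <- generate_scene(spec, "det")
  s2 <- generate_scene(spec, "det")
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$truth_labels, s2$truth_labels)

  r <- sqrt(s1$truth$radius_a * s1$truth$radius_b)   # equivalent radius
  expect_true(all(r >= spec$radius_range[1] - 1e-9 &
                    r <= spec$radius_range[2] + 1e-9))
  expect_true(all(s1$truth$intensity >= spec$intensity_range[1] &
                    s1$truth$intensity <= spec$intensity_range[2]))
  expect_true(all(s1$image$pixels >= 0 & s1$image$pixels <= 65535))
})

test_that("ground truth is conserved between markers, labels and tables", {
  sc <- generate_scene(small_spec(seed = 92L, n_cells = 14L), "gt")
  expect_equal(nrow(sc$markers), 14L)
  expect_equal(nrow(sc$truth), 14L)
  expect_equal(max(sc$truth_labels), 14L)
  # every marker inside its own object's mask
  hit <- sc$truth_labels[cbind(sc$markers$y + 1L, sc$markers$x + 1L)]
  expect_identical(hit, seq_len(14L))
})

test_that("an empty scene has no cells and a component count matches truth", {
  empty <- generate_scene(small_spec(seed = 93L, n_cells = 0L), "none")
  expect_equal(nrow(empty$markers), 0L)
  expect_true(all(empty$truth_labels == 0L))

  sc <- generate_scene(synthetic_spec(width = 256L, height = 256L,
                                      n_cells = 50L, radius_range = c(5, 8),
                                      seed = 94L), "fifty")
  comp <- oracle_flood_fill(sc$truth_labels > 0L, 8)
  expect_equal(max(comp), 50L)
})

test_that("infeasible packings and invalid specs are rejected", {
  expect_error(generate_scene(synthetic_spec(width = 64L, height = 64L,
                                             n_cells = 200L,
                                             radius_range = c(6, 8),
                                             seed = 95L)),
               "infeasible packing")
  expect_error(synthetic_spec(radius_range = c(5, 3)), "radius_range")
  expect_error(synthetic_spec(overlap_fraction = 2), "overlap_fraction")
  expect_error(synthetic_spec(width = 20L, height = 20L) |> generate_scene(),
               "too small")
})

test_that("overlapping pairs are placed closer than separated cells", {
  spec <- synthetic_spec(width = 192L, height = 192L, n_cells = 20L,
                         radius_range = c(5, 7), overlap_fraction = 0.5,
                         seed = 96L)
  sc <- generate_scene(spec, "pairs")
  d <- as.matrix(dist(cbind(sc$truth$x, sc$truth$y)))
  diag(d) <- Inf
  nearest <- apply(d, 1, min)
  # with 5 touching pairs, at least 10 cells have a neighbor within 1.8 radii
  expect_gte(sum(nearest <= 1.8 * max(spec$radius_range)), 10L)
})

test_that("artifacts and gradient fields are rendered on demand", {
  spec <- small_spec(seed = 97L, n_cells = 5L, n_speckles = 10L,
                     n_smears = 1L, gradient = TRUE)
  sc <- generate_scene(spec, "art")
  plain <- generate_scene(small_spec(seed = 97L, n_cells = 5L), "plain")
  # artifacts brighten pixels outside the truth mask
  out <- sc$truth_labels == 0L
  expect_gt(mean(sc$image$pixels[out]), mean(plain$image$pixels[out]))
  # markers still only for true cells
  expect_equal(nrow(sc$markers), 5L)
})

test_that("two-group experiments realize the requested density ratio", {
  specA <- synthetic_spec(width = 128L, height = 128L, n_cells = 8L,
                          radius_range = c(4, 6), seed = 98L)
  specB <- synthetic_spec(width = 128L, height = 128L, n_cells = 12L,
                          radius_range = c(4, 6), seed = 99L)
  ex <- generate_experiment(specA, specB, n_images_per_group = 20L)
  expect_equal(nrow(ex$table), 40L)
  # Poisson-sampled counts around the two means
  cA <- ex$table$true_count[ex$table$group == "A"]
  cB <- ex$table$true_count[ex$table$group == "B"]
  expect_gt(stats::var(cA), 0)
  mA <- mean(cA); mB <- mean(cB)
  # realized mean-count ratio near 1.5, judged against its own sampling
  # error (delta method) since the per-image means are small here
  se_ratio <- (mB / mA) * sqrt(stats::var(cA) / (20 * mA^2) +
                                 stats::var(cB) / (20 * mB^2))
  expect_lt(abs(mB / mA - 1.5), 3 * se_ratio)

  same <- generate_experiment(specA, specA, n_images_per_group = 2L,
                              group_names = c("x", "y"))
  tt <- same$table
  expect_equal(mean(tt$true_count[tt$group == "x"]),
               mean(tt$true_count[tt$group == "y"]))
  one <- generate_experiment(specA, specB, n_images_per_group = 1L)
  expect_equal(length(one$scenes), 2L)
})

test_that("fixture bundles hit disk in the standard layout and reload", {
  dirp <- file.path(tempdir(), "bundle")
  unlink(dirp, recursive = TRUE)
  specA <- small_spec(seed = 101L, n_cells = 6L)
  specB <- small_spec(seed = 102L, n_cells = 9L)
  ex <- generate_experiment(specA, specB, n_images_per_group = 2L)
  write_scene_bundle(ex, dirp)
  expect_length(list.files(file.path(dirp, "images")), 4L)
  expect_length(list.files(file.path(dirp, "markers")), 4L)
  tt <- read_results_table(file.path(dirp, "truth_table.csv"))
  expect_equal(nrow(tt), 4L)
  img <- read_image(file.path(dirp, "images", "A_01.tif"))
  expect_identical(img$pixels, ex$scenes$A_01$image$pixels)
  mk <- read_markers(file.path(dirp, "markers", "A_01.csv"), dim(img))
  expect_equal(as.data.frame(mk), as.data.frame(ex$scenes$A_01$markers),
               ignore_attr = TRUE)
})
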