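test_that("scene generation is bytewise deterministic for a fixed seed", {
  sp <- small_scene_spec(17, n_kernels = 6L)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_identical(a$clean_mask, b$clean_mask)
  # a different seed changes the scene
  c <- generate_scene(small_scene_spec(18, n_kernels = 6L))
  expect_false(identical(a$image, c$image))
})

test_that("a single intact kernel scene is a single labelled ellipse", {
  sp <- scene_spec(
    image_width = 400L, image_height = 300L, n_kernels = 1L,
    damage_fraction = 0, speckle_density = 0, rng_seed = 5
  )
  sc <- generate_scene(sp)
  expect_identical(sc$truth$true_count, 1L)
  expect_identical(sc$truth$damage_labels, "intact")
  expect_identical(length(sc$truth$masks), 1L)
  expect_identical(dim(sc$image), c(300L, 400L, 3L))
  expect_true(max(sc$image) <= 255L && min(sc$image) >= 0L)
  # exactly one connected foreground component
  expect_identical(length(extract_contours(sc$clean_mask)), 1L)
})

test_that("forced adhesion yields one touching cluster with shared id", {
  sp <- scene_spec(
    image_width = 500L, image_height = 400L, n_kernels = 2L,
    adhesion_probability = 1, damage_fraction = 0, speckle_density = 0,
    rng_seed = 3
  )
  sc <- generate_scene(sp)
  expect_identical(sc$truth$cluster_ids[1], sc$truth$cluster_ids[2])
  # masks overlap by at least one pixel
  lm <- truth_label_map(sc$truth, dim(sc$clean_mask))
  fg1 <- sum(sc$truth$masks[[1]]$mask)
  fg2 <- sum(sc$truth$masks[[2]]$mask)
  expect_gte(fg1 + fg2 - sum(sc$clean_mask), 1) # union smaller than the sum
  expect_identical(length(extract_contours(sc$clean_mask)), 1L)
})

test_that("instance masks union reproduces the clean foreground exactly", {
  sc <- generate_scene(small_scene_spec(23, n_kernels = 10L))
  expect_identical(truth_foreground(sc$truth, dim(sc$clean_mask)), sc$clean_mask)
})

test_that("damaged kernels carry a concavity at least as deep as the drawn minimum", {
  mind <- min(small_scene_spec(1)$bite_depth_range)
  found <- 0L
  for (s in 1:3) {
    sc <- generate_scene(small_scene_spec(900 + s, n_kernels = 8L))
    for (k in which(sc$truth$damage_labels == "damaged")) {
      m <- sc$truth$masks[[k]]$mask
      crop <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
      crop[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m * 1L
      dfs <- find_defects(extract_contours(crop)[[1]], 1)
      expect_gte(max(dfs$depth), mind - 1)
      found <- found + 1L
    }
  }
  expect_gt(found, 3L)
})

test_that("an overcrowded frame raises a capacity error", {
  sp <- scene_spec(
    image_width = 220L, image_height = 180L, n_kernels = 40L,
    adhesion_probability = 0, rng_seed = 1
  )
  expect_error(generate_scene(sp), class = "maizeseg_capacity_error")
})

test_that("spec invariants are validated", {
  expect_error(scene_spec(n_kernels = 0), "n_kernels")
  expect_error(scene_spec(kernel_axis_range = c(2, 10)), "semi-axis")
  expect_error(scene_spec(damage_fraction = 1.2), "damage_fraction")
  expect_error(
    scene_spec(background_level = 200, kernel_level_range = c(210, 220)),
    "bimodal"
  )
})

test_that("the feature dataset splits whole images 80/20 without leakage", {
  specs <- lapply(1:10, function(s) {
    scene_spec(
      image_width = 360L, image_height = 280L, n_kernels = 4L,
      adhesion_probability = 0.5, damage_fraction = 0.3, overlap_cap = 0.3,
      rng_seed = 700 + s
    )
  })
  ds <- generate_feature_dataset(specs, split_fraction = 0.8, rng_seed = 9)
  expect_identical(length(ds$train_scenes), 8L)
  expect_identical(length(ds$test_scenes), 2L)
  expect_length(intersect(ds$train_scenes, ds$test_scenes), 0)
  expect_setequal(unique(ds$train$scene), ds$train_scenes)
  expect_setequal(unique(ds$test$scene), ds$test_scenes)
  expect_identical(nrow(ds$train), 8L * 4L)
  # determinism of the assignment
  ds2 <- generate_feature_dataset(specs, split_fraction = 0.8, rng_seed = 9)
  expect_identical(ds$train_scenes, ds2$train_scenes)
  expect_identical(ds$train, ds2$train)
  # minimal split
  ds3 <- generate_feature_dataset(specs[1:2], split_fraction = 0.5, rng_seed = 1)
  expect_identical(length(ds3$train_scenes), 1L)
  expect_identical(length(ds3$test_scenes), 1L)
  expect_error(generate_feature_dataset(specs, split_fraction = 1.2), "split_fraction")
  expect_error(generate_feature_dataset(specs[1], split_fraction = 0.5), "empty")
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_scene(small_scene_spec(2, n_kernels = 3L)))
  after <- runif(3)
  expect_identical(before, after)
})
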