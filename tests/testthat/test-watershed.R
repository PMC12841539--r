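test_that("Sobel gradient matches hand convolution on canonical inputs", {
  g0 <- sobel_gradient(matrix(37L, 10, 10))
  expect_true(all(g0$gx == 0) && all(g0$gy == 0) && all(g0$g == 0))
  # vertical step 0|255: pixel one column left of the edge sees |gx| = 4*255
  img <- matrix(0L, 10, 10)
  img[, 6:10] <- 255L
  g <- sobel_gradient(img)
  expect_equal(abs(g$gx[5, 5]), 4 * 255)
  expect_equal(g$gy[5, 5], 0)
  expect_equal(max(g$g), 255) # magnitude rescaled
})

test_that("transposing the image swaps the gradient components", {
  set.seed(21)
  img <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
  g1 <- sobel_gradient(img)
  g2 <- sobel_gradient(t(img))
  expect_equal(abs(g1$gx), abs(t(g2$gy)), tolerance = 1e-12)
  expect_equal(abs(g1$gy), abs(t(g2$gx)), tolerance = 1e-12)
  expect_equal(g1$g, t(g2$g), tolerance = 1e-12)
})

test_that("Gaussian smoothing conserves mass and never raises the maximum", {
  m <- matrix(55, 12, 12)
  expect_equal(smooth_gradient(m, 1.5, rescale = FALSE), m, tolerance = 1e-12)
  imp <- matrix(0, 21, 21)
  imp[11, 11] <- 1
  sm <- smooth_gradient(imp, 1.5, rescale = FALSE)
  expect_equal(sum(sm), 1, tolerance = 1e-6) # mass conserved
  r <- ceiling(3 * 1.5)
  k <- exp(-((-r:r)^2) / (2 * 1.5^2))
  k <- k / sum(k)
  expect_equal(sm[11, 11], max(k)^2, tolerance = 1e-9) # separable peak
  set.seed(3)
  noisy <- matrix(runif(400, 0, 255), 20, 20)
  expect_lte(max(smooth_gradient(noisy, 1.5, rescale = FALSE)), max(noisy))
  expect_error(smooth_gradient(noisy, -1), "positive")
})

test_that("distance transform is exact (brute-force oracle) and zero on background", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rbinom(24 * 24, 1, runif(1, 0.3, 0.8)), 24, 24)
    m[1, 1] <- 0L
    expect_equal(distance_transform(m), edt_bruteforce(m), tolerance = 1e-9)
  }
  p <- matrix(0L, 9, 9)
  p[5, 5] <- 1L
  d <- distance_transform(p)
  expect_equal(d[5, 5], 1) # nearest 4-neighbour is background
  expect_true(all(d[p == 0L] == 0))
  expect_error(distance_transform(matrix(1L, 4, 4)), "background")
})

test_that("marker extraction finds one core per object", {
  m2 <- disks_mask(rbind(c(40, 40), c(40, 110)), 25, 80, 150)
  mk <- extract_markers(distance_transform(m2))
  expect_identical(attr(mk, "n_markers"), 2L)
  m1 <- disk_mask(20)
  for (pf in c(0.2, 0.4, 0.7)) {
    mk1 <- extract_markers(distance_transform(m1), peak_fraction = pf)
    expect_identical(attr(mk1, "n_markers"), 1L)
  }
  # overlapping pair with clearly separate cores
  mo <- disks_mask(rbind(c(40, 45), c(40, 95)), 28, 80, 140)
  expect_identical(attr(extract_markers(distance_transform(mo)), "n_markers"), 2L)
  expect_error(extract_markers(matrix(0, 5, 5)), "no markers")
})

test_that("the component-max marker rule is available and sane", {
  m2 <- disks_mask(rbind(c(40, 40), c(40, 110)), 25, 80, 150)
  mk <- extract_markers(distance_transform(m2), method = "component_max")
  expect_identical(attr(mk, "n_markers"), 2L)
})

test_that("flooding is marker-conservative and labels the whole foreground", {
  m <- disks_mask(rbind(c(40, 45), c(40, 100)), 26, 80, 150)
  d <- distance_transform(m)
  mk <- extract_markers(d)
  lab <- watershed_flood(mk, m)
  expect_setequal(setdiff(unique(as.vector(lab)), c(0L, -1L)), seq_len(attr(mk, "n_markers")))
  merged <- merge_watershed_lines(lab)
  expect_true(all(merged[m == 1L] > 0L)) # partition of the mask
  expect_true(all(merged[m == 0L] == 0L)) # no leak into background
  # markers keep their labels
  expect_true(all(lab[mk > 0L] == mk[mk > 0L]))
})

test_that("a single marker floods the whole component", {
  m <- disk_mask(15)
  mk <- extract_markers(distance_transform(m))
  lab <- merge_watershed_lines(watershed_flood(mk, m))
  expect_true(all(lab[m == 1L] == 1L))
})

test_that("two symmetric objects split near the symmetry axis", {
  m <- disks_mask(rbind(c(60, 60), c(60, 124)), 40, 120, 190)
  ws <- watershed_segment(m)
  expect_identical(max(ws$labels), 2L)
  s1 <- sum(ws$labels == 1L)
  s2 <- sum(ws$labels == 2L)
  expect_lt(abs(s1 - s2) / max(s1, s2), 0.05)
})

test_that("flood input contracts are enforced", {
  m <- disk_mask(10)
  mk <- matrix(0L, nrow(m), ncol(m))
  expect_error(watershed_flood(mk, m), "at least one marker")
  mk[1, 1] <- 1L # background corner
  expect_error(watershed_flood(mk, m), "inside the mask")
})

test_that("watershed alone separates most adhered pairs within the operating range", {
  sep <- 0L
  n <- 40L
  for (s in seq_len(n)) {
    sp <- scene_spec(
      image_width = 400L, image_height = 300L, n_kernels = 2L,
      adhesion_probability = 1, damage_fraction = 0, speckle_density = 0,
      illumination_slope = 0, overlap_cap = 0.3, rng_seed = s
    )
    sc <- generate_scene(sp)
    ws <- watershed_segment(sc$clean_mask)
    if (max(ws$labels) == 2L) sep <- sep + 1L
  }
  expect_gte(sep / n, 0.9)
})
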