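test_that("grayscale conversion applies the luma weights with half-up rounding", {
  px <- function(r, g, b) array(c(r, g, b), c(1L, 1L, 3L))
  expect_equal(to_grayscale(px(100, 100, 100))[1, 1], 100L) # weights sum to 1
  expect_equal(to_grayscale(px(255, 0, 0))[1, 1], 76L) # 0.299*255 = 76.245
  expect_equal(to_grayscale(px(0, 255, 0))[1, 1], 150L) # 0.587*255 = 149.685
  expect_equal(to_grayscale(px(0, 0, 255))[1, 1], 29L) # 0.114*255 = 29.07
  z <- array(0L, c(4L, 5L, 3L))
  expect_true(all(to_grayscale(z) == 0L))
  g <- matrix(7L, 3L, 3L)
  expect_warning(out <- to_grayscale(g), "single-channel")
  expect_identical(out, g)
})

test_that("Otsu threshold maximises inter-class variance (brute-force oracle)", {
  set.seed(101)
  for (i in 1:25) {
    img <- matrix(sample(0:255, 12 * 12, replace = TRUE), 12, 12)
    expect_identical(otsu_threshold(img)$t_optimal, otsu_bruteforce(img))
  }
  # bimodal image: threshold separates the two modes
  img <- matrix(c(rep(40L, 100), rep(200L, 156)), 16, 16)
  t <- otsu_threshold(img)$t_optimal
  expect_gte(t, 40L)
  expect_lt(t, 200L)
})

test_that("Otsu ties break to the smallest threshold and the mean identity holds", {
  # equal counts of 0 and 255: every t in 0..254 attains the maximum
  img <- matrix(c(rep(0L, 128), rep(255L, 128)), 16, 16)
  o <- otsu_threshold(img)
  expect_identical(o$t_optimal, 0L)
  # omega1*mu1 + omega2*mu2 = mu at every threshold
  set.seed(11)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  o <- otsu_threshold(img)
  recon <- o$omega1 * o$mu1 + o$omega2 * o$mu2
  expect_true(all(abs(recon - o$mu) < 1e-9))
  expect_true(all(o$sigma_b2 >= -1e-12))
  expect_equal(sum(o$p), 1, tolerance = 1e-12)
})

test_that("constant images are rejected by Otsu", {
  expect_error(otsu_threshold(matrix(128L, 8, 8)), "degenerate")
})

test_that("binarize thresholds with the configured polarity", {
  expect_true(all(binarize(matrix(200L, 4, 4), 100) == 1L))
  expect_true(all(binarize(matrix(50L, 4, 4), 100) == 0L))
  expect_true(all(binarize(matrix(50L, 4, 4), 100, polarity = "dark") == 1L))
  expect_error(binarize(matrix(50L, 4, 4), 300), "threshold")
  # threshold object accepted directly
  img <- matrix(c(rep(40L, 100), rep(200L, 156)), 16, 16)
  o <- otsu_threshold(img)
  expect_equal(sum(binarize(img, o)), 156)
})

test_that("binarization of a synthetic scene recovers the clean foreground", {
  sc <- generate_scene(small_scene_spec(3, n_kernels = 6L))
  pp <- preprocess_image(sc$image)
  truth_px <- sum(sc$clean_mask)
  expect_lt(abs(sum(pp$mask) - truth_px) / truth_px, 0.05)
})

test_that("erosion and dilation follow their set definitions", {
  # single-anchor-pixel structuring element: both are the identity
  se1 <- struct_elem(matrix(TRUE, 1, 1))
  set.seed(5)
  a <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_identical(erode(a, se1), a * 1L)
  expect_identical(dilate(a, se1), a * 1L)
  # dilating a single pixel by a 3x3 box paints the 3x3 neighbourhood
  p <- matrix(0L, 7, 7)
  p[4, 4] <- 1L
  d <- dilate(p, se_box(3))
  expect_equal(sum(d), 9)
  expect_true(all(d[3:5, 3:5] == 1L))
  expect_error(struct_elem(matrix(FALSE, 3, 3)), "at least one")
})

test_that("morphology identities hold on random masks", {
  set.seed(77)
  interior <- 3:14
  for (i in 1:20) {
    # a 2-px background margin keeps the object clear of the image border,
    # where the finite-domain background convention breaks the identities
    a <- matrix(0L, 16, 16)
    a[interior, interior] <- rbinom(12 * 12, 1, runif(1, 0.3, 0.7))
    se <- if (i %% 2) se_box(3) else se_cross(3)
    # duality: complement of dilation = erosion of complement by reflection
    # (compared on the interior; complementing flips the border convention)
    d1 <- (1L - dilate(a, se))[interior, interior]
    d2 <- erode(1L - a, se_reflect(se))[interior, interior]
    expect_identical(d1, d2)
    # opening idempotence
    op <- opening(a, se)
    expect_identical(opening(op, se), op)
    # extensivity ordering: opening <= A <= closing
    expect_true(all(op <= a))
    expect_true(all(a <= closing(a, se)))
  }
})

test_that("opening removes speckles and closing fills pinholes", {
  m <- matrix(0L, 12, 12)
  m[6, 6] <- 1L # isolated speckle
  expect_true(all(opening(m, se_box(3)) == 0L))
  m2 <- matrix(0L, 12, 12)
  m2[3:10, 3:10] <- 1L
  m2[6, 6] <- 0L # pinhole
  expect_equal(closing(m2, se_box(3))[6, 6], 1L)
})
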