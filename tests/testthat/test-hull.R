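test_that("convex hull contains every input point (half-plane oracle)", {
  set.seed(9)
  for (i in 1:10) {
    pts <- cbind(sample(0:60, 50, replace = TRUE), sample(0:60, 50, replace = TRUE))
    hull <- convex_hull(pts)
    h <- nrow(hull)
    # every point lies on the inner side of (or on) every hull edge
    s <- shoelace_signed(hull)
    for (k in seq_len(h)) {
      a <- hull[k, ]
      b <- hull[if (k < h) k + 1L else 1L, ]
      cr <- (b[2] - a[2]) * (pts[, 1] - a[1]) - (b[1] - a[1]) * (pts[, 2] - a[2])
      if (s > 0) expect_true(all(cr >= -1e-9)) else expect_true(all(cr <= 1e-9))
    }
    # hull vertices are a subset of the input vertices
    expect_true(all(attr(hull, "indices") %in% seq_len(nrow(pts))))
  }
})

test_that("hull handles canonical cases and rejects degenerate input", {
  sq <- rbind(c(0, 0), c(0, 9), c(9, 9), c(9, 0), c(4, 5)) # square + interior point
  hull <- convex_hull(sq)
  expect_setequal(attr(hull, "indices"), 1:4)
  line <- cbind(0:5, 0:5)
  expect_error(convex_hull(line), "collinear")
  expect_error(convex_hull(rbind(c(0, 0), c(1, 1))), "at least 3")
})

test_that("defect depth equals the point-to-line distance", {
  expect_equal(defect_depth(c(0, 0), c(0, 10), c(4, 5)), 4.0)
  expect_equal(defect_depth(c(0, 0), c(4, 3), c(0, 3)), 2.4) # |3*0-4*3|/5
  expect_equal(defect_depth(c(0, 0), c(10, 10), c(5, 5)), 0) # collinear
  expect_error(defect_depth(c(1, 1), c(1, 1), c(0, 0)), "must differ")
  set.seed(13)
  for (i in 1:1000) {
    a <- runif(2, -50, 50)
    b <- runif(2, -50, 50)
    c0 <- runif(2, -50, 50)
    if (sum((a - b)^2) < 1e-6) next
    expect_equal(defect_depth(a, b, c0), point_line_dist(a, b, c0), tolerance = 1e-9)
  }
})

test_that("convex shapes yield no defects; fused disks yield the two neck notches", {
  ct <- extract_contours(disk_mask(20))[[1]]
  expect_identical(nrow(find_defects(ct, 8)), 0L)
  expect_identical(nrow(find_defects(ct, Inf)), 0L)
  # two fused r=20 disks, centres 32 px apart: notch depth r - sqrt(r^2-16^2) = 8
  m <- disks_mask(rbind(c(30, 30), c(30, 62)), 20, 60, 92)
  ctf <- extract_contours(m)[[1]]
  dfs <- find_defects(ctf, 7)
  expect_identical(nrow(dfs), 2L)
  expect_true(all(dfs$depth >= 7))
  # the two notches sit on opposite sides of the neck, near column 46
  expect_gt(abs(diff(dfs$far_row)), 20)
  expect_true(all(abs(dfs$far_col - 46) < 4))
})

test_that("splitting cuts fused objects and leaves convex objects alone", {
  m1 <- disk_mask(18)
  r1 <- split_at_defects(m1, 8)
  expect_identical(length(r1$contours), 1L)
  expect_identical(r1$mask, m1)

  m2 <- disks_mask(rbind(c(30, 30), c(30, 62)), 20, 60, 92)
  r2 <- split_at_defects(m2, 8)
  expect_identical(length(r2$contours), 2L)
  single <- sum(disk_mask(20))
  for (ct in r2$contours) {
    expect_lt(abs(contour_area(ct) - single) / single, 0.10)
  }
  # area conservation: only the cut line is lost
  expect_lte(sum(m2) - sum(r2$mask), 2 * 45)

  # staggered chain of three fused ellipses (as scattered kernels lie)
  m3 <- ellipse_mask_at(100, 220, 50, 45, 32, 22) |
    ellipse_mask_at(100, 220, 38, 100, 32, 22) |
    ellipse_mask_at(100, 220, 52, 155, 32, 22)
  r3 <- split_at_defects(m3 * 1L, 8)
  expect_identical(length(r3$contours), 3L)
})

test_that("splitting never decreases the contour count", {
  set.seed(31)
  for (i in 1:5) {
    sc <- generate_scene(small_scene_spec(400 + i, n_kernels = 5L))
    n0 <- length(extract_contours(sc$clean_mask))
    res <- split_at_defects(sc$clean_mask, 8)
    expect_gte(length(res$contours), n0)
  }
})

test_that("threshold selects adhesion necks and ignores wrinkle-scale dents", {
  # necks: fused disks at several overlaps, every notch depth > 8
  deep <- 0L
  total <- 0L
  for (gap in c(26, 30, 34)) {
    m <- disks_mask(rbind(c(40, 40), c(40, 40 + gap)), 22, 80, 130)
    dfs <- find_defects(extract_contours(m)[[1]], 1)
    dfs <- dfs[dfs$depth > 6, , drop = FALSE] # the two neck notches
    total <- total + nrow(dfs)
    deep <- deep + sum(dfs$depth >= 8)
  }
  expect_identical(deep, total) # 100% of true necks selected at 8
  # wrinkle: a 3-px dent on a disk stays below the threshold
  m <- disk_mask(22)
  m[25 + 0:1, 4:8] <- 0L # shallow boundary nick
  dfs <- find_defects(extract_contours(m)[[1]], 1)
  expect_true(nrow(dfs) == 0L || max(dfs$depth) < 8)
  expect_identical(nrow(find_defects(extract_contours(m)[[1]], 8)), 0L)
})

test_that("object counting applies the area floor", {
  expect_identical(count_objects(list()), 0L)
  m <- disks_mask(rbind(c(30, 30), c(30, 90)), 20, 60, 120)
  m[5, 5] <- 1L # debris pixel
  cts <- extract_contours(m)
  expect_identical(count_objects(cts), 2L) # adaptive floor removes debris
  expect_identical(count_objects(cts, min_area = 0), 3L)
  expect_error(count_objects(cts, min_area = -1), "non-negative")
})
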