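# Printed reference values for kernel shape descriptors (major axis, minor
# axis, elongation, eccentricity). The reference table truncates displayed
# ratios to 4 decimals, so the comparisons below truncate too.
ref_normal <- matrix(c(
  114.294, 94.005, 1.2158, 0.5687,
  113.013, 86.321, 1.3092, 0.6454,
  119.809, 90.955, 1.3172, 0.6508,
  117.046, 106.027, 1.1039, 0.4235,
  113.437, 88.448, 1.2825, 0.6261,
  121.329, 98.219, 1.2352, 0.5870,
  119.295, 83.833, 1.4230, 0.7114,
  111.992, 95.969, 1.1669, 0.5154,
  120.169, 88.628, 1.3558, 0.6753,
  118.402, 95.609, 1.2383, 0.5898
), ncol = 4, byrow = TRUE)

trunc4 <- function(x) trunc(x * 1e4) / 1e4

test_that("elongation and eccentricity reproduce the reference table rows", {
  for (i in seq_len(nrow(ref_normal))) {
    expect_identical(trunc4(elongation(ref_normal[i, 1], ref_normal[i, 2])), ref_normal[i, 3])
    expect_identical(trunc4(eccentricity(ref_normal[i, 1], ref_normal[i, 2])), ref_normal[i, 4])
  }
  # damaged-kernel row with printed axes 109.714 / 46.028
  expect_identical(trunc4(elongation(109.714, 46.028)), 2.3836)
  # limits
  expect_equal(elongation(10, 10), 1.0)
  expect_equal(eccentricity(10, 10), 0)
})

test_that("compactness satisfies the isoperimetric identities", {
  r <- 5
  expect_equal(compactness(pi * r^2, 2 * pi * r), 1.0) # ideal circle
  s <- 7
  expect_equal(compactness(s^2, 4 * s), pi / 4) # square
  expect_equal(roughness(pi * r^2, 2 * pi * r), 1.0)
  expect_equal(roughness(s^2, 4 * s), 4 / pi)
})

test_that("digital disk descriptors approach their analytic values", {
  ct <- extract_contours(disk_mask(20))[[1]]
  area <- contour_area(ct)
  per <- contour_perimeter(ct)
  expect_lt(abs(area - pi * 400) / (pi * 400), 0.02)
  expect_lt(abs(per - 2 * pi * 20) / (2 * pi * 20), 0.08)
  ax <- principal_axes(ct)
  expect_lt(abs(ax["major"] - 40) / 40, 0.02)
  expect_lt(abs(ax["minor"] - 40) / 40, 0.02)
  expect_lt(abs(rectangularity(ct) - pi / 4), 0.03 * pi / 4)
  expect_lte(compactness(area, per), 1 + 0.05)
})

test_that("rectangle descriptors are exact", {
  m <- matrix(0L, 20, 34)
  m[5:14, 5:28] <- 1L # 10 x 24 block
  ct <- extract_contours(m)[[1]]
  expect_equal(rectangularity(ct), 1.0, tolerance = 1e-9)
  expect_equal(contour_area(ct), 240)
  expect_equal(contour_perimeter(ct), 2 * (9 + 23))
  ax <- principal_axes(ct)
  expect_equal(unname(ax["major"]), sqrt(9^2 + 23^2), tolerance = 1e-9) # diagonal
})

test_that("the minimum-area rectangle never exceeds the bounding box", {
  set.seed(17)
  for (i in 1:10) {
    pts <- cbind(sample(0:40, 30, TRUE), sample(0:40, 30, TRUE))
    hull <- convex_hull(pts)
    bbox <- (max(pts[, 1]) - min(pts[, 1])) * (max(pts[, 2]) - min(pts[, 2]))
    expect_lte(maizeseg:::min_area_rect(hull), bbox + 1e-9)
  }
})

test_that("descriptors are translation invariant and rotation stable", {
  m <- ellipse_mask_at(100, 130, 50, 60, 40, 27)
  ct <- extract_contours(m)[[1]]
  ct2 <- ct
  ct2[, 1] <- ct2[, 1] + 13L
  ct2[, 2] <- ct2[, 2] + 5L
  attr(ct2, "area") <- attr(ct, "area")
  expect_equal(principal_axes(ct), principal_axes(ct2))
  expect_equal(contour_perimeter(ct), contour_perimeter(ct2))
  expect_equal(rectangularity(ct), rectangularity(ct2))
  # same ellipse rotated 30 degrees: axes change < 2%
  mr <- ellipse_mask_at(120, 130, 60, 65, 40, 27, theta = pi / 6)
  ctr <- extract_contours(mr)[[1]]
  a1 <- principal_axes(ct)
  a2 <- principal_axes(ctr)
  expect_lt(abs(a1["major"] - a2["major"]) / a1["major"], 0.02)
  expect_lt(abs(a1["minor"] - a2["minor"]) / a1["minor"], 0.02)
})

test_that("pixel area matches the shoelace polygon within the digitization bound", {
  set.seed(23)
  shapes <- list(disk_mask(12), ellipse_mask_at(60, 80, 30, 40, 25, 15, 0.4))
  for (m in shapes) {
    ct <- extract_contours(m)[[1]]
    expect_lte(abs(contour_area(ct) - shoelace_area(ct)),
               contour_perimeter(ct) / 2 + 1)
  }
})

test_that("kernel records satisfy their invariants on generated scenes", {
  sc <- generate_scene(small_scene_spec(71, n_kernels = 8L))
  recs <- scene_truth_features(sc)
  expect_identical(nrow(recs), 8L)
  expect_true(all(recs$area > 0))
  expect_true(all(recs$perimeter > 0))
  expect_true(all(recs$major_axis >= recs$minor_axis))
  expect_true(all(recs$minor_axis > 0))
  expect_true(all(recs$elongation >= 1))
  expect_true(all(recs$eccentricity >= 0 & recs$eccentricity < 1))
  expect_true(all(recs$rectangularity > 0 & recs$rectangularity <= 1 + 1e-9))
  expect_identical(extract_features(list()), extract_features(list())) # empty ok
  expect_identical(nrow(extract_features(list())), 0L)
})

test_that("damaged kernels are smaller and more elongated than intact ones", {
  recs <- do.call(rbind, lapply(1:6, function(s) {
    scene_truth_features(generate_scene(small_scene_spec(500 + s, n_kernels = 10L)))
  }))
  dam <- recs[recs$label == "damaged", ]
  ok <- recs[recs$label == "intact", ]
  expect_gt(nrow(dam), 5)
  expect_lt(mean(dam$area), mean(ok$area))
  expect_gt(mean(dam$elongation), mean(ok$elongation))
  expect_gt(mean(dam$eccentricity), mean(ok$eccentricity))
})

test_that("the canonical CSV schema round-trips", {
  sc <- generate_scene(small_scene_spec(81, n_kernels = 5L))
  recs <- scene_truth_features(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(recs, path)
  back <- read.csv(path)
  expect_identical(
    names(back),
    c("id", "area", "perimeter", "major_axis", "minor_axis", "elongation",
      "rectangularity", "eccentricity", "compactness", "label")
  )
  expect_equal(back$area, recs$area)
})
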