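#' Principal axes of a contour
#'
#' Major axis: the largest distance between any two hull vertices (the
#' rotating-calipers diameter of the shape). Minor axis: the maximal extent
#' of the contour measured perpendicular to the major-axis direction.
#'
#' @param contour contour matrix of `(row, col)` points.
#' @return named numeric vector `c(major, minor)`.
#' @export
principal_axes <- function(contour) {
  hull <- convex_hull(contour) # errors on collinear degenerate input
  h <- nrow(hull)
  best <- c(0, 1L, 2L)
  for (i in 1:(h - 1L)) {
    d2 <- (hull[(i + 1L):h, 1] - hull[i, 1])^2 + (hull[(i + 1L):h, 2] - hull[i, 2])^2
    j <- which.max(d2)
    if (d2[j] > best[1]) best <- c(d2[j], i, i + j)
  }
  major <- sqrt(best[1])
  u <- (hull[best[3], ] - hull[best[2], ]) / major
  perp <- c(-u[2], u[1])
  proj <- contour[, 1] * perp[1] + contour[, 2] * perp[2]
  minor <- max(proj) - min(proj)
  c(major = major, minor = minor)
}

#' Shape descriptor ratios
#'
#' The dimensionless descriptors used for damage classification:
#' * `elongation(major, minor)` = major / minor (>= 1);
#' * `eccentricity(major, minor)` = sqrt(1 - minor^2 / major^2), in `[0, 1)`;
#' * `compactness(area, perimeter)` = 4 pi area / perimeter^2 (1 for an ideal
#'   circle, smaller for rough or elongated shapes);
#' * `roughness(area, perimeter)` = its reciprocal, perimeter^2 / (4 pi area);
#' * `rectangularity(contour)` = polygon area / area of the minimum-area
#'   rotated enclosing rectangle, in `(0, 1]`.
#'
#' `rectangularity()` measures both numerator and denominator on the polygon
#' through the boundary pixel centres (shoelace area and calipers rectangle
#' of the hull), so a filled axis-aligned rectangle scores exactly 1.
#'
#' @param major,minor axis lengths in px, `major >= minor > 0`.
#' @param area area in px^2.
#' @param perimeter boundary length in px.
#' @param contour contour matrix of `(row, col)` points.
#' @param polygon_area optional numerator override for `rectangularity()`;
#'   defaults to [shoelace_area()] of the contour.
#' @name shape_ratios
NULL

#' @rdname shape_ratios
#' @export
elongation <- function(major, minor) {
  stopifnot(minor > 0)
  major / minor
}

#' @rdname shape_ratios
#' @export
eccentricity <- function(major, minor) {
  stopifnot(major > 0)
  sqrt(pmax(0, 1 - minor^2 / major^2))
}

#' @rdname shape_ratios
#' @export
compactness <- function(area, perimeter) {
  stopifnot(perimeter > 0)
  4 * pi * area / perimeter^2
}

#' @rdname shape_ratios
#' @export
roughness <- function(area, perimeter) 1 / compactness(area, perimeter)

#' @rdname shape_ratios
#' @export
rectangularity <- function(contour, polygon_area = NULL) {
  hull <- convex_hull(contour)
  a <- polygon_area %||% shoelace_area(contour)
  mra <- min_area_rect(hull)
  a / mra
}

# minimum-area enclosing rotated rectangle by rotating calipers: one side of
# the optimum is collinear with a hull edge
min_area_rect <- function(hull) {
  h <- nrow(hull)
  y <- hull[, 1]
  x <- hull[, 2]
  best <- Inf
  for (i in seq_len(h)) {
    j <- if (i < h) i + 1L else 1L
    ex <- x[j] - x[i]
    ey <- y[j] - y[i]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    ex <- ex / len
    ey <- ey / len
    u <- x * ex + y * ey
    v <- -x * ey + y * ex
    area <- (max(u) - min(u)) * (max(v) - min(v))
    if (area < best) best <- area
  }
  best
}

# the eight feature columns of a kernel record, in canonical order
feature_columns <- function() {
  c(
    "area", "perimeter", "major_axis", "minor_axis",
    "elongation", "rectangularity", "eccentricity", "compactness"
  )
}

#' Extract kernel records from segmented instances
#'
#' Computes the eight morphological descriptors (area, perimeter, major and
#' minor axis, elongation, rectangularity, eccentricity, compactness) for
#' every contour, one record per separated kernel. Degenerate contours
#' (fewer than 3 points, or collinear) are skipped.
#'
#' @param contours list of contours from [extract_contours()].
#' @param labels character vector of class labels per contour (recycled
#'   `"unknown"` when missing).
#' @return data frame with columns `id`, the eight features, `roughness`
#'   (reciprocal compactness, reported for comparability) and `label`.
#' @export
extract_features <- function(contours, labels = NULL) {
  rows <- lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    if (nrow(ct) < 3L) return(NULL)
    axes <- tryCatch(principal_axes(ct), error = function(e) NULL)
    if (is.null(axes) || axes["minor"] <= 0) return(NULL)
    area <- contour_area(ct)
    per <- contour_perimeter(ct)
    if (per <= 0 || area <= 0) return(NULL)
    data.frame(
      id = attr(ct, "id") %||% i,
      area = area,
      perimeter = per,
      major_axis = unname(axes["major"]),
      minor_axis = unname(axes["minor"]),
      elongation = unname(elongation(axes["major"], axes["minor"])),
      rectangularity = rectangularity(ct),
      eccentricity = unname(eccentricity(axes["major"], axes["minor"])),
      compactness = compactness(area, per),
      roughness = roughness(area, per),
      label = if (is.null(labels)) "unknown" else labels[i]
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      id = integer(), area = numeric(), perimeter = numeric(),
      major_axis = numeric(), minor_axis = numeric(), elongation = numeric(),
      rectangularity = numeric(), eccentricity = numeric(),
      compactness = numeric(), roughness = numeric(), label = character()
    )
  }
  rownames(out) <- NULL
  out
}

#' Write kernel records in the canonical CSV schema
#'
#' Columns: `id,area,perimeter,major_axis,minor_axis,elongation,`
#' `rectangularity,eccentricity,compactness,label`.
#'
#' @param records data frame from [extract_features()].
#' @param path output file.
#' @export
write_features_csv <- function(records, path) {
  cols <- c("id", feature_columns(), "label")
  write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
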