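#' Extract object contours from a mask or label map
#'
#' Traces the outer boundary of every labelled region (8-connected foreground,
#' Moore border following). Contours are closed ordered polygons of 0-based
#' `(row, col)` pixel coordinates, oriented counter-clockwise in image
#' coordinates (row axis pointing down).
#'
#' @param x 0/1 mask (components are labelled first, 8-connectivity) or an
#'   integer label map with instances `1..K`.
#' @param min_pixels drop regions with fewer pixels than this (default 1).
#' @return list of contour matrices; each carries attributes `id` (region
#'   label) and `area` (region pixel count).
#' @export
extract_contours <- function(x, min_pixels = 1L) {
  storage.mode(x) <- "integer"
  labs <- if (max(x) <= 1L) cpp_label_components(x, 8L) else x
  ids <- sort(unique(labs[labs > 0L]))
  sizes <- tabulate(labs[labs > 0L], nbins = max(labs))
  out <- list()
  for (id in ids) {
    if (sizes[id] < min_pixels) next
    ct <- cpp_trace_boundary(labs, id)
    ct <- orient_ccw(ct)
    attr(ct, "id") <- id
    attr(ct, "area") <- sizes[id]
    out[[length(out) + 1L]] <- ct
  }
  out
}

# enforce counter-clockwise orientation in image coordinates (y = row, down):
# visually-CCW loops have negative shoelace sum in (x = col, y = row)
orient_ccw <- function(contour) {
  if (nrow(contour) < 3L) return(contour)
  s <- shoelace_signed(contour)
  if (s > 0) contour[rev(seq_len(nrow(contour))), , drop = FALSE] else contour
}

shoelace_signed <- function(contour) {
  y <- contour[, 1]
  x <- contour[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  0.5 * sum(x * y[j] - x[j] * y)
}

#' Polygon (shoelace) area of a contour
#'
#' The continuous area of the polygon through the boundary pixel centres.
#' This underestimates the pixel-count area by roughly half the perimeter
#' (boundary pixels straddle the polygon edge); use [contour_area()] for the
#' pixel count.
#'
#' @param contour contour matrix (rows are `(row, col)` points).
#' @return polygon area in px^2.
#' @export
shoelace_area <- function(contour) abs(shoelace_signed(contour))

#' Pixel-count area enclosed by a contour
#'
#' Counts the pixels enclosed by (and on) the closed contour, by flood-filling
#' the complement from the border of the bounding box: an 8-connected closed
#' boundary cannot be crossed by a 4-connected background flood.
#'
#' @param contour contour matrix of 0-based `(row, col)` points.
#' @return number of pixels on or inside the contour.
#' @export
contour_area <- function(contour) {
  a <- attr(contour, "area")
  if (!is.null(a)) return(as.numeric(a))
  if (nrow(contour) == 1L) return(1)
  r0 <- min(contour[, 1]); c0 <- min(contour[, 2])
  nr <- max(contour[, 1]) - r0 + 3L # one-pixel pad all around
  nc <- max(contour[, 2]) - c0 + 3L
  grid <- matrix(1L, nr, nc)
  grid[cbind(contour[, 1] - r0 + 2L, contour[, 2] - c0 + 2L)] <- 0L
  comp <- cpp_label_components(grid, 4L)
  outside <- comp[1, 1] # pad corner is always outside
  sum(comp != outside)
}

#' Chain-length perimeter of a contour
#'
#' Sum of Euclidean steps along the closed boundary chain: 1 per axial move,
#' sqrt(2) per diagonal move.
#'
#' @param contour contour matrix of `(row, col)` points.
#' @return perimeter in px (0 for a single-pixel contour).
#' @export
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt((contour[j, 1] - contour[, 1])^2 + (contour[j, 2] - contour[, 2])^2))
}

# 4-connected (supercover-style) line rasterisation between two 0-based
# (row, col) points; returns a matrix of points including both endpoints
line_pixels <- function(p, q) {
  dr <- q[1] - p[1]
  dc <- q[2] - p[2]
  n <- max(abs(dr), abs(dc))
  if (n == 0L) return(matrix(p, 1L, 2L))
  rs <- p[1] + seq(0, 1, length.out = n + 1L) * dr
  cs <- p[2] + seq(0, 1, length.out = n + 1L) * dc
  ri <- round(rs)
  ci <- round(cs)
  pts <- cbind(ri, ci)
  # insert an intermediate axial pixel at every diagonal step
  extra <- NULL
  for (k in seq_len(nrow(pts) - 1L)) {
    if (pts[k + 1L, 1] != pts[k, 1] && pts[k + 1L, 2] != pts[k, 2]) {
      extra <- rbind(extra, c(pts[k + 1L, 1], pts[k, 2]))
    }
  }
  pts <- rbind(pts, extra)
  pts[!duplicated(pts), , drop = FALSE]
}
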