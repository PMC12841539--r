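#' Convex hull of a contour
#'
#' The smallest convex polygon containing all input points; vertices are a
#' subset of the input vertices, returned in convex polygon order.
#'
#' @param contour contour matrix of `(row, col)` points.
#' @return hull contour matrix with attribute `indices` (row indices into the
#'   input, in the same polygon order).
#' @export
convex_hull <- function(contour) {
  if (nrow(contour) < 3L) stop("contour must have at least 3 points")
  idx <- unique(grDevices::chull(contour[, 2], contour[, 1]))
  if (length(idx) < 3L) stop("degenerate contour: all points are collinear")
  out <- contour[idx, , drop = FALSE]
  attr(out, "indices") <- idx
  out
}

#' Depth of a point below a hull edge
#'
#' Perpendicular distance from contour point `C` to the hull edge through
#' `A` and `B`, by the vector cross product:
#' `|(Bx-Ax)(Cy-Ay) - (By-Ay)(Cx-Ax)| / |AB|`.
#'
#' @param a,b hull edge endpoints, length-2 numeric `(row, col)`.
#' @param c0 contour point, length-2 numeric.
#' @return depth in pixels (>= 0).
#' @export
defect_depth <- function(a, b, c0) {
  if (all(a == b)) stop("hull edge endpoints must differ")
  cross <- (b[2] - a[2]) * (c0[1] - a[1]) - (b[1] - a[1]) * (c0[2] - a[2])
  abs(cross) / sqrt((b[1] - a[1])^2 + (b[2] - a[2])^2)
}

#' Convexity defects of a contour
#'
#' For every hull edge, finds the contour point of maximal depth on the arc
#' the edge subtends, and keeps those at or above `depth_threshold` -- the
#' candidate adhesion points between touching kernels. Returned sorted by
#' decreasing depth.
#'
#' @param contour contour matrix of `(row, col)` points.
#' @param depth_threshold minimum depth in pixels (default 8).
#' @return data frame with one row per defect: `start_idx`, `end_idx`
#'   (contour indices of the hull edge), `far_idx` (deepest contour point),
#'   `far_row`, `far_col` and `depth`. Zero rows when the contour is convex
#'   at this threshold.
#' @export
find_defects <- function(contour, depth_threshold = 8) {
  if (depth_threshold <= 0) stop("depth_threshold must be positive")
  empty <- data.frame(
    start_idx = integer(), end_idx = integer(), far_idx = integer(),
    far_row = integer(), far_col = integer(), depth = numeric()
  )
  if (nrow(contour) < 4L) return(empty)
  hull <- tryCatch(convex_hull(contour), error = function(e) NULL)
  if (is.null(hull)) return(empty)
  # hull vertices of a simple closed curve occur in cyclic traversal order,
  # so sorting by contour index recovers the arc structure
  hidx <- sort(attr(hull, "indices"))
  n <- nrow(contour)
  res <- empty
  for (k in seq_along(hidx)) {
    i1 <- hidx[k]
    i2 <- if (k < length(hidx)) hidx[k + 1L] else hidx[1L]
    arc <- if (i1 < i2) {
      if (i2 - i1 < 2L) next else (i1 + 1L):(i2 - 1L)
    } else {
      # wrap-around arc
      w <- c(if (i1 < n) (i1 + 1L):n else integer(), if (i2 > 1L) 1L:(i2 - 1L) else integer())
      if (length(w) == 0L) next else w
    }
    a <- contour[i1, ]
    b <- contour[i2, ]
    cross <- (b[2] - a[2]) * (contour[arc, 1] - a[1]) -
      (b[1] - a[1]) * (contour[arc, 2] - a[2])
    depths <- abs(cross) / sqrt(sum((b - a)^2))
    j <- which.max(depths)
    if (depths[j] >= depth_threshold) {
      res <- rbind(res, data.frame(
        start_idx = i1, end_idx = i2, far_idx = arc[j],
        far_row = contour[arc[j], 1], far_col = contour[arc[j], 2],
        depth = depths[j]
      ))
    }
  }
  res[order(-res$depth), , drop = FALSE]
}

#' Split adhered objects by cutting between convexity defects
#'
#' Iteratively resolves adhesions in a binary mask: the deepest remaining
#' defect is paired with the nearest other defect point of the same contour
#' such that the connecting segment lies entirely inside the foreground, and
#' a one-pixel background cut is drawn along it (a 4-connected line, which an
#' 8-connected foreground cannot bridge). A defect with no compatible partner
#' is cut along its depth direction to the nearest boundary point, but only
#' when that cut is short relative to the defect depth
#' (`fallback_len_factor`), so an isolated concavity -- e.g. a damage bite on
#' a single kernel -- is left alone rather than bisecting the object.
#' Contours are re-extracted after every cut until no actionable defect
#' remains or the iteration cap is hit.
#'
#' @param mask 0/1 matrix.
#' @param depth_threshold minimum defect depth in pixels (default 8).
#' @param max_iter_per_contour iteration cap per initial contour (default 10).
#' @param fallback_len_factor maximum fallback cut length as a multiple of
#'   the defect depth (default 0.8).
#' @param min_piece reject cuts that create a fragment smaller than this many
#'   pixels (default 0 = no check).
#' @param partner_depth_min smallest defect depth admissible as a cut
#'   partner (default 5 px, just above wrinkle-scale false defects); cuts
#'   are only ever initiated at defects of at least `depth_threshold`.
#' @return list with `mask` (cut mask), `labels` (final 8-connected instance
#'   labels) and `contours` (see [extract_contours()]).
#' @export
split_at_defects <- function(mask, depth_threshold = 8,
                             max_iter_per_contour = 10L,
                             fallback_len_factor = 0.8, min_piece = 0L,
                             partner_depth_min = 5) {
  mask <- (mask != 0) * 1L
  comp <- cpp_label_components(mask, 8L)
  ncomp <- attr(comp, "n_labels")
  out <- mask
  for (id in seq_len(ncomp)) {
    w <- which(comp == id, arr.ind = TRUE)
    r0 <- min(w[, 1]); r1 <- max(w[, 1])
    c0 <- min(w[, 2]); c1 <- max(w[, 2])
    crop <- matrix(0L, r1 - r0 + 3L, c1 - c0 + 3L)
    crop[cbind(w[, 1] - r0 + 2L, w[, 2] - c0 + 2L)] <- 1L
    crop <- split_crop(crop, depth_threshold, max_iter_per_contour,
                       fallback_len_factor, min_piece, partner_depth_min)
    sel <- (comp[r0:r1, c0:c1] == id)
    block <- out[r0:r1, c0:c1]
    block[sel] <- crop[2:(r1 - r0 + 2L), 2:(c1 - c0 + 2L)][sel]
    out[r0:r1, c0:c1] <- block
  }
  labels <- cpp_label_components(out, 8L)
  list(mask = out, labels = labels, contours = extract_contours(labels))
}

# iterative defect cutting on a padded single-component crop
split_crop <- function(crop, depth_threshold, max_iter_per_contour,
                       fallback_len_factor, min_piece = 0L,
                       partner_depth_min = 5) {
  rejected <- matrix(numeric(0), 0L, 2L)
  iter <- 0L
  cap <- max_iter_per_contour
  repeat {
    iter <- iter + 1L
    if (iter > cap) {
      warning("defect-splitting iteration cap reached; returning current state")
      break
    }
    labs <- cpp_label_components(crop, 8L)
    nl <- attr(labs, "n_labels")
    cap <- max(cap, max_iter_per_contour * nl)
    best <- NULL
    best_contour <- NULL
    for (id in seq_len(nl)) {
      ct <- orient_ccw(cpp_trace_boundary(labs, id))
      if (nrow(ct) < 8L) next
      # cuts are initiated at defects >= depth_threshold, but the partner
      # point may be any defect above the false-defect band (wrinkle-scale
      # concavities stay below ~5 px; genuine adhesion notches exceed it)
      dfs <- find_defects(ct, min(partner_depth_min, depth_threshold))
      if (nrow(dfs) == 0L || dfs$depth[1] < depth_threshold) next
      dfs <- dfs[!is_rejected(dfs, rejected), , drop = FALSE]
      if (nrow(dfs) == 0L || dfs$depth[1] < depth_threshold) next
      if (is.null(best) || dfs$depth[1] > best$depth[1]) {
        best <- dfs
        best_contour <- ct
      }
    }
    if (is.null(best)) break
    d1 <- best[1L, ]
    cut <- find_cut(crop, best_contour, best, d1, fallback_len_factor)
    ok <- FALSE
    if (!is.null(cut)) {
      cand <- crop
      cand[cut] <- 0L
      if (min_piece <= 0L) {
        ok <- TRUE
      } else {
        # accept only if no new undersized fragment is created
        sz <- tabulate(cpp_label_components(cand, 8L))
        ok <- all(sz >= min_piece) || sum(sz < min_piece) <= sum(tabulate(labs) < min_piece)
      }
      if (ok) crop <- cand
    }
    if (!ok) rejected <- rbind(rejected, c(d1$far_row, d1$far_col))
  }
  crop
}

# no background pixel within `rad` (Chebyshev) of point `pt` (1-based)
clearance_ok <- function(crop, pt, rad) {
  r0 <- max(1L, pt[1] - rad); r1 <- min(nrow(crop), pt[1] + rad)
  c0 <- max(1L, pt[2] - rad); c1 <- min(ncol(crop), pt[2] + rad)
  all(crop[r0:r1, c0:c1] == 1L)
}

is_rejected <- function(dfs, rejected) {
  if (nrow(rejected) == 0L) return(rep(FALSE, nrow(dfs)))
  vapply(seq_len(nrow(dfs)), function(i) {
    any((rejected[, 1] - dfs$far_row[i])^2 + (rejected[, 2] - dfs$far_col[i])^2 <= 4)
  }, logical(1))
}

# choose the cut for the deepest defect d1: nearest compatible partner defect,
# else a short fallback cut along the depth direction; returns an index matrix
# of crop pixels to clear, or NULL if no admissible cut exists
find_cut <- function(crop, contour, dfs, d1, fallback_len_factor) {
  p <- c(d1$far_row, d1$far_col)
  depth_dir <- function(row) {
    mid <- (contour[row$start_idx, ] + contour[row$end_idx, ]) / 2
    v <- c(row$far_row, row$far_col) - mid
    n <- sqrt(sum(v^2))
    if (n < 1e-9) c(0, 0) else v / n
  }
  v1 <- depth_dir(d1)
  if (nrow(dfs) > 1L) {
    others <- dfs[-1L, , drop = FALSE]
    dist2 <- (others$far_row - p[1])^2 + (others$far_col - p[2])^2
    for (k in order(dist2)) {
      q <- c(others$far_row[k], others$far_col[k])
      if (sum((q - p)^2) < 4) next
      # partner defects must point towards each other, not share one notch
      v2 <- depth_dir(others[k, ])
      if (sum(v1 * v2) > 0.3) next
      # and the cut must continue both intrusion directions (a neck cut runs
      # notch-to-notch through the pinch, not sideways across a kernel)
      u <- (q - p) / sqrt(sum((q - p)^2))
      if (sum(u * v1) < 0.4 || sum(-u * v2) < 0.4) next
      pix <- line_pixels(p, q) + 1L # contours are 0-based, crop matrix 1-based
      if (!all(crop[pix] == 1L)) next
      # the cut must pass through the interior, not hug the background
      len <- sqrt(sum((q - p)^2))
      rad <- max(2L, min(4L, floor(0.25 * len)))
      mid <- round((p + q) / 2) + 1L
      if (!clearance_ok(crop, mid, rad)) next
      return(pix)
    }
  }
  # fallback: march from the defect point along the inward depth direction
  a <- contour[d1$start_idx, ]
  b <- contour[d1$end_idx, ]
  mid <- (a + b) / 2
  v <- p - mid
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) return(NULL)
  v <- v / nv
  maxlen <- fallback_len_factor * d1$depth
  q <- NULL
  for (s in seq_len(ceiling(maxlen) + 1L)) {
    cand <- round(p + s * v) + 1L
    if (cand[1] < 1 || cand[1] > nrow(crop) || cand[2] < 1 || cand[2] > ncol(crop) ||
        crop[cand[1], cand[2]] == 0L) {
      q <- round(p + (s - 1L) * v)
      break
    }
  }
  if (is.null(q)) return(NULL) # still inside foreground after maxlen: too long
  if (sum((q - p)^2) < 1) return(NULL)
  pix <- line_pixels(p, q) + 1L
  if (all(crop[pix] == 1L)) pix else NULL
}

#' Refine watershed basins by convexity-defect splitting
#'
#' Applies [split_at_defects()] to each basin of a watershed label map,
#' resolving residual adhesions the flooding stage left merged.
#'
#' @param labels instance label map (no boundary codes; see
#'   [merge_watershed_lines()]).
#' @param depth_threshold,max_iter_per_contour,fallback_len_factor passed to
#'   [split_at_defects()].
#' @param min_piece smallest admissible fragment a cut may create; default
#'   15% of the median basin area (the same floor [count_objects()] uses).
#' @param partner_depth_min smallest defect depth admissible as a cut
#'   partner, see [split_at_defects()].
#' @return relabelled instance map (`1..K`, 0 background).
#' @export
refine_labels <- function(labels, depth_threshold = 8,
                          max_iter_per_contour = 10L,
                          fallback_len_factor = 0.8, min_piece = NULL,
                          partner_depth_min = 5) {
  storage.mode(labels) <- "integer"
  if (is.null(min_piece)) {
    sizes <- tabulate(labels[labels > 0L])
    sizes <- sizes[sizes > 0L]
    min_piece <- if (length(sizes)) 0.15 * median(sizes) else 0L
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  nxt <- 0L
  for (id in sort(unique(labels[labels > 0L]))) {
    w <- which(labels == id, arr.ind = TRUE)
    r0 <- min(w[, 1]); r1 <- max(w[, 1])
    c0 <- min(w[, 2]); c1 <- max(w[, 2])
    crop <- matrix(0L, r1 - r0 + 3L, c1 - c0 + 3L)
    crop[cbind(w[, 1] - r0 + 2L, w[, 2] - c0 + 2L)] <- 1L
    res <- split_at_defects(crop, depth_threshold, max_iter_per_contour,
                            fallback_len_factor, min_piece = min_piece,
                            partner_depth_min = partner_depth_min)
    sub <- res$labels[2:(r1 - r0 + 2L), 2:(c1 - c0 + 2L), drop = FALSE]
    sel <- sub > 0L
    block <- out[r0:r1, c0:c1]
    block[sel] <- sub[sel] + nxt
    out[r0:r1, c0:c1] <- block
    nxt <- nxt + max(sub)
  }
  out
}

#' Count objects from a contour list
#'
#' Number of contours whose enclosed pixel area reaches `min_area`. With the
#' default `min_area = NULL`, the floor is 15% of the median contour area in
#' the scene, which suppresses debris and cut slivers without an absolute
#' size assumption.
#'
#' @param contours list of contours (see [extract_contours()]).
#' @param min_area absolute area floor in px^2, or NULL for the adaptive
#'   default.
#' @return integer count.
#' @export
count_objects <- function(contours, min_area = NULL) {
  if (length(contours) == 0L) return(0L)
  areas <- vapply(contours, contour_area, numeric(1))
  if (is.null(min_area)) min_area <- 0.15 * median(areas)
  if (min_area < 0) stop("min_area must be non-negative")
  sum(areas >= min_area)
}
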