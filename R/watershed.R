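#' Sobel gradient of a grayscale image
#'
#' Convolves with the 3x3 Sobel templates
#' (x: `[[-1,0,1],[-2,0,2],[-1,0,1]]`, y: its transpose), computes the
#' magnitude `G = sqrt(Gx^2 + Gy^2)` and linearly rescales it to `[0, 255]`.
#' Borders are replicate-padded. Here "x" is the column (horizontal)
#' direction and "y" the row (vertical) direction.
#'
#' @param img single-channel raster image.
#' @return list of class `gradient_field` with numeric matrices `gx`, `gy`
#'   (signed responses) and `g` (magnitude, rescaled to `[0, 255]`).
#' @export
sobel_gradient <- function(img) {
  img <- as_raster(img)
  if (n_channels(img) != 1L) stop("sobel_gradient() expects a grayscale image")
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  sh <- function(dr, dc) shift_replicate(m, dr, dc)
  # gx: horizontal derivative (columns); gy: vertical derivative (rows)
  gx <- (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1)) * -1 +
    (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1))
  gy <- (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) * -1 +
    (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1))
  g <- sqrt(gx^2 + gy^2)
  structure(list(gx = gx, gy = gy, g = rescale_255(g)), class = "gradient_field")
}

# replicate-padded shift: out(i,j) = m(clamp(i - dr), clamp(j - dc))
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

rescale_255 <- function(m) {
  mx <- max(m)
  if (mx > 0) m * (255 / mx) else m
}

#' Gaussian smoothing of a gradient magnitude
#'
#' Convolves the magnitude with a truncated Gaussian kernel
#' (radius `ceiling(3 sigma)`, replicate-padded, separable) and rescales the
#' result back to `[0, 255]`.
#'
#' @param g a `gradient_field` from [sobel_gradient()], or a bare numeric
#'   matrix.
#' @param sigma Gaussian standard deviation in pixels (default 1.5).
#' @param rescale rescale the smoothed magnitude to `[0, 255]` (default TRUE).
#' @return same type as the input, with the magnitude smoothed.
#' @export
smooth_gradient <- function(g, sigma = 1.5, rescale = TRUE) {
  if (sigma <= 0) stop("sigma must be positive")
  m <- if (inherits(g, "gradient_field")) g$g else g
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  sm <- convolve_sep(m, k)
  if (rescale) sm <- rescale_255(sm)
  if (inherits(g, "gradient_field")) {
    g$g <- sm
    g
  } else {
    sm
  }
}

# separable convolution with replicate padding
convolve_sep <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (d in -r:r) out <- out + k[d + r + 1L] * shift_replicate(m, d, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (d in -r:r) out <- out + k[d + r + 1L] * shift_replicate(m2, 0L, d)
  out
}

#' Exact Euclidean distance transform
#'
#' For every pixel, the Euclidean distance to the nearest background (0)
#' pixel: `D(x, y) = min over background (x', y') of sqrt((x-x')^2+(y-y')^2)`.
#' Computed exactly with a two-pass lower-envelope algorithm.
#'
#' @param mask 0/1 matrix with at least one background pixel.
#' @return numeric matrix of distances (0 on background).
#' @export
distance_transform <- function(mask) {
  mask <- (mask != 0) * 1L
  if (all(mask == 1L)) stop("mask has no background pixel; distances are undefined")
  cpp_exact_edt(mask)
}

#' Extract watershed markers from a distance field
#'
#' Kernel cores appear as peaks of the Euclidean distance transform. The
#' default method (`"peaks"`) grows regions downhill from every regional
#' maximum and merges two regions when the saddle between them is high
#' relative to the lower peak (`saddle >= saddle_ratio * peak`) or when the
#' lower peak's prominence is below `prominence_min` pixels -- suppressing
#' the spurious ridge maxima of a digitised distance field while keeping
#' genuinely distinct cores apart. Each surviving region contributes one
#' marker: its pixels with `D >= peak_fraction * peak`.
#'
#' The `"component_max"` method instead thresholds each connected foreground
#' component at `peak_fraction` of that component's global maximum. It is
#' simpler but cannot both separate strongly overlapping pairs and retain
#' markers for small kernels in mixed-size clusters; see the package
#' vignette.
#'
#' @param d distance field from [distance_transform()].
#' @param peak_fraction marker core level as a fraction of the region peak
#'   (default 0.4).
#' @param method `"peaks"` (default) or `"component_max"`.
#' @param saddle_ratio relative saddle level above which two peak regions are
#'   merged (default 0.95; `"peaks"` method only).
#' @param prominence_min absolute prominence in pixels below which a peak is
#'   merged into its neighbour (default 3; `"peaks"` method only).
#' @param min_area drop marker cores smaller than this many pixels (default
#'   5), except that every foreground component keeps at least its strongest
#'   marker.
#' @return integer label matrix, markers labelled `1..K` (0 elsewhere), with
#'   attribute `n_markers`.
#' @export
extract_markers <- function(d, peak_fraction = 0.4,
                            method = c("peaks", "component_max"),
                            saddle_ratio = 0.95, prominence_min = 3,
                            min_area = 5L) {
  method <- match.arg(method)
  if (peak_fraction <= 0 || peak_fraction >= 1) {
    stop("peak_fraction must lie in (0, 1)")
  }
  fg <- (d > 0) * 1L
  if (method == "component_max") {
    comp <- cpp_label_components(fg, 8L)
    ncomp <- attr(comp, "n_labels")
    core <- matrix(0L, nrow(d), ncol(d))
    for (k in seq_len(ncomp)) {
      sel <- comp == k
      core[sel & d >= peak_fraction * max(d[sel])] <- 1L
    }
    markers <- cpp_label_components(core, 8L)
  } else {
    pr <- cpp_peak_regions(d, saddle_ratio, prominence_min)
    regions <- pr$labels
    # core level: peak_fraction of the region peak, but always strictly above
    # the highest saddle separating the region from a neighbour, so marker
    # cores never annex the neck between two kernels
    lev_vec <- pmax(peak_fraction * pr$peaks, pr$maxsad + 0.5)
    core <- matrix(0L, nrow(d), ncol(d))
    lev <- lev_vec[ifelse(regions > 0L, regions, NA)]
    dim(lev) <- dim(regions)
    sel <- regions > 0L & d >= lev
    core[sel] <- 1L
    markers <- cpp_label_components(core, 8L)
    # one marker per peak region: collapse any split cores inside a region
    markers <- collapse_by_region(markers, regions)
  }
  markers <- drop_small_markers(markers, fg, min_area)
  if (attr(markers, "n_markers") == 0L) {
    stop("no markers found; lower peak_fraction or check the mask polarity")
  }
  markers
}

# keep one marker id per peak region (largest core), then relabel 1..K
collapse_by_region <- function(markers, regions) {
  ids <- which(markers > 0L)
  if (length(ids) == 0L) {
    attr(markers, "n_markers") <- 0L
    return(markers)
  }
  reg <- regions[ids]
  markers[ids] <- reg
  relabel_sequential(markers)
}

relabel_sequential <- function(markers) {
  ids <- sort(unique(markers[markers > 0L]))
  out <- matrix(0L, nrow(markers), ncol(markers))
  out[markers > 0L] <- match(markers[markers > 0L], ids)
  attr(out, "n_markers") <- length(ids)
  out
}

# drop marker labels whose core is tiny, but never leave a foreground
# component markerless
drop_small_markers <- function(markers, fg, min_area) {
  ids <- markers[markers > 0L]
  if (length(ids) == 0L) {
    attr(markers, "n_markers") <- 0L
    return(markers)
  }
  sizes <- tabulate(ids)
  small <- which(sizes > 0L & sizes < min_area)
  if (length(small)) {
    comp <- cpp_label_components(fg, 8L)
    # component of each marker label (markers never straddle components)
    keep <- rep(TRUE, length(sizes))
    keep[small] <- FALSE
    lab_comp <- vapply(seq_along(sizes), function(l) {
      w <- which(markers == l)[1]
      if (is.na(w)) NA_integer_ else comp[w]
    }, integer(1))
    for (cmp in unique(lab_comp[!is.na(lab_comp)])) {
      in_comp <- which(lab_comp == cmp)
      if (!any(keep[in_comp])) {
        # retain the largest core so the component stays reachable
        keep[in_comp[which.max(sizes[in_comp])]] <- TRUE
      }
    }
    idx <- which(markers > 0L)
    markers[idx[!keep[markers[idx]]]] <- 0L
  }
  relabel_sequential(markers)
}

#' Marker-controlled watershed flooding
#'
#' Priority-floods the height surface from the markers, restricted to the
#' mask: pixels are popped in increasing height order (ties broken by
#' insertion order, so the result is deterministic), each taking the label of
#' the basin that reached it; pixels reached by two basins simultaneously
#' become watershed-line pixels with the reserved boundary code `-1`. With
#' the default `height = NULL` the negated distance transform of the mask is
#' used, so flooding proceeds from kernel cores outward.
#'
#' @param markers integer marker label matrix (from [extract_markers()]).
#' @param mask 0/1 foreground mask.
#' @param height numeric height surface (e.g. a smoothed Sobel magnitude for
#'   gradient-based flooding); default `NULL` uses `-distance_transform(mask)`.
#' @return integer label matrix: 0 background, `1..K` basins, `-1` watershed
#'   lines.
#' @export
watershed_flood <- function(markers, mask, height = NULL) {
  mask <- (mask != 0) * 1L
  if (inherits(height, "gradient_field")) height <- height$g
  if (is.null(height)) height <- -distance_transform(mask)
  if (!all(dim(height) == dim(mask))) stop("height and mask sizes differ")
  if (!any(markers > 0L)) stop("at least one marker is required")
  if (any(markers > 0L & mask == 0L)) stop("markers must lie inside the mask")
  storage.mode(markers) <- "integer"
  cpp_watershed_flood(height, markers, mask)
}

#' Merge watershed-line pixels into adjacent basins
#'
#' Assigns every boundary-coded pixel (-1) to the neighbouring basin with the
#' lowest label, so each basin is a closed region suitable for contour
#' extraction.
#'
#' @param labels label matrix from [watershed_flood()].
#' @return label matrix without boundary codes.
#' @export
merge_watershed_lines <- function(labels) {
  storage.mode(labels) <- "integer"
  cpp_merge_boundary(labels)
}

#' Watershed segmentation of a binary mask
#'
#' Distance transform, marker extraction and flooding in one call. With
#' `max_rounds > 1` the segmentation is applied recursively: each basin is
#' re-examined with its own distance transform (its cut faces now count as
#' background, so neck saddles are no longer inflated by neighbouring
#' kernels) and re-flooded whenever new markers appear. Rounds stop when no
#' basin splits further.
#'
#' @param mask 0/1 foreground mask.
#' @param peak_fraction,method,saddle_ratio,prominence_min,min_area passed to
#'   [extract_markers()].
#' @param height optional flooding height (see [watershed_flood()]); only
#'   used for the first round.
#' @param max_rounds maximum number of recursive splitting rounds (default
#'   3; 1 = single classical pass).
#' @return list with `distance`, `markers` (first round) and `labels`
#'   (boundary lines merged).
#' @export
watershed_segment <- function(mask, peak_fraction = 0.4, method = "peaks",
                              saddle_ratio = 0.95, prominence_min = 3,
                              min_area = 5L, height = NULL, max_rounds = 3L) {
  mask <- (mask != 0) * 1L
  d <- distance_transform(mask)
  markers <- extract_markers(d,
    peak_fraction = peak_fraction, method = method,
    saddle_ratio = saddle_ratio, prominence_min = prominence_min,
    min_area = min_area
  )
  labels <- watershed_flood(markers, mask, height = height %||% -d)
  labels <- merge_watershed_lines(labels)
  round <- 1L
  while (round < max_rounds) {
    round <- round + 1L
    split_any <- FALSE
    nxt <- max(labels)
    for (id in seq_len(max(labels))) {
      w <- which(labels == id, arr.ind = TRUE)
      if (nrow(w) == 0L) next
      r0 <- min(w[, 1]); r1 <- max(w[, 1])
      c0 <- min(w[, 2]); c1 <- max(w[, 2])
      crop <- matrix(0L, r1 - r0 + 3L, c1 - c0 + 3L)
      crop[cbind(w[, 1] - r0 + 2L, w[, 2] - c0 + 2L)] <- 1L
      dc <- cpp_exact_edt(crop)
      mk <- tryCatch(
        extract_markers(dc,
          peak_fraction = peak_fraction, method = method,
          saddle_ratio = saddle_ratio, prominence_min = prominence_min,
          min_area = min_area
        ),
        error = function(e) NULL
      )
      if (is.null(mk) || attr(mk, "n_markers") < 2L) next
      sub <- merge_watershed_lines(watershed_flood(mk, crop, height = -dc))
      sub <- sub[2:(r1 - r0 + 2L), 2:(c1 - c0 + 2L), drop = FALSE]
      sel <- sub > 1L
      if (!any(sel)) next
      split_any <- TRUE
      block <- labels[r0:r1, c0:c1]
      block[sel] <- sub[sel] + nxt - 1L # label 1 keeps id, others renumber
      labels[r0:r1, c0:c1] <- block
      nxt <- nxt + max(sub) - 1L
    }
    if (!split_any) break
  }
  labels <- relabel_sequential(labels)
  attr(labels, "n_markers") <- NULL
  list(distance = d, markers = markers, labels = labels)
}
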