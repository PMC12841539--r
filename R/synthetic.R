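#' Specification of a synthetic adhered-kernel scene
#'
#' Describes one simulated acquisition: bright elliptical kernels scattered
#' on a dark matte background, with a controllable fraction of touching
#' (adhered) kernels, a fraction carrying a concave damage bite, a mild
#' linear illumination gradient and specular salt-and-pepper speckles. The
#' defaults emulate a bench-top inspection image: a 2000 x 1500 px frame with
#' ~120 kernels of 40-60 px semi-axes, half of them placed against an already
#' placed neighbour, 30% damaged.
#'
#' @param image_width,image_height frame size in px.
#' @param n_kernels number of kernels (>= 1).
#' @param adhesion_probability probability in `[0, 1]` that a kernel is
#'   placed touching an existing kernel.
#' @param damage_fraction fraction of kernels given a damage bite.
#' @param kernel_axis_range `(min, max)` ellipse semi-axes in px (min >= 4).
#' @param bite_depth_range `(min, max)` maximum inward bite depth in px.
#' @param background_level background gray level (0-255).
#' @param kernel_level_range `(min, max)` kernel gray level; the minimum must
#'   exceed `background_level + 30` so the histogram stays bimodal.
#' @param illumination_slope linear illumination gradient in gray per px
#'   (applied along the horizontal axis).
#' @param speckle_density fraction of pixels replaced by specular speckles.
#' @param overlap_cap maximum overlap between two adhered kernels as a
#'   fraction of the smaller kernel's area (default 0.45).
#' @param rng_seed integer seed; every stochastic choice in the generator
#'   flows from it.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_width = 2000L, image_height = 1500L,
                       n_kernels = 120L, adhesion_probability = 0.5,
                       damage_fraction = 0.3, kernel_axis_range = c(40, 60),
                       bite_depth_range = c(22, 42), background_level = 30L,
                       kernel_level_range = c(140, 200),
                       illumination_slope = 0.008, speckle_density = 5e-4,
                       overlap_cap = 0.45, rng_seed = 1L) {
  spec <- list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    n_kernels = as.integer(n_kernels),
    adhesion_probability = adhesion_probability,
    damage_fraction = damage_fraction,
    kernel_axis_range = as.numeric(kernel_axis_range),
    bite_depth_range = as.numeric(bite_depth_range),
    background_level = as.numeric(background_level),
    kernel_level_range = as.numeric(kernel_level_range),
    illumination_slope = illumination_slope,
    speckle_density = speckle_density,
    overlap_cap = overlap_cap,
    rng_seed = as.integer(rng_seed)
  )
  if (spec$n_kernels < 1L) stop("n_kernels must be >= 1")
  if (spec$kernel_axis_range[1] < 4) stop("minimum kernel semi-axis is 4 px")
  if (diff(spec$kernel_axis_range) < 0) stop("kernel_axis_range must be (min, max)")
  for (f in c("adhesion_probability", "damage_fraction", "speckle_density", "overlap_cap")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (spec$kernel_level_range[1] <= spec$background_level + 30) {
    stop("kernel gray levels must exceed background_level + 30 (bimodal histogram)")
  }
  structure(spec, class = "scene_spec")
}

# rasterise a rotated filled ellipse; returns NULL if fully off-image,
# else list(bbox = c(r0, r1, c0, c1) 1-based clipped, mask = logical crop)
rasterize_ellipse <- function(cr, cc, a, b, theta, h, w) {
  ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2) # half-extent in cols
  ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2) # half-extent in rows
  r0 <- max(1L, floor(cr - ey)); r1 <- min(h, ceiling(cr + ey))
  c0 <- max(1L, floor(cc - ex)); c1 <- min(w, ceiling(cc + ex))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1
  cols <- c0:c1
  dy <- matrix(rows - cr, length(rows), length(cols))
  dx <- matrix(cols - cc, length(rows), length(cols), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  list(bbox = c(r0, r1, c0, c1), mask = u^2 + v^2 <= 1)
}

# pixel overlap of two bbox-cropped masks
crop_overlap <- function(k1, k2) {
  b1 <- k1$bbox; b2 <- k2$bbox
  r0 <- max(b1[1], b2[1]); r1 <- min(b1[2], b2[2])
  c0 <- max(b1[3], b2[3]); c1 <- min(b1[4], b2[4])
  if (r0 > r1 || c0 > c1) return(0L)
  m1 <- k1$mask[(r0:r1) - b1[1] + 1L, (c0:c1) - b1[3] + 1L, drop = FALSE]
  m2 <- k2$mask[(r0:r1) - b2[1] + 1L, (c0:c1) - b2[3] + 1L, drop = FALSE]
  sum(m1 & m2)
}

# do two cropped masks touch (8-adjacency) or overlap?
crops_touch <- function(k1, k2) {
  b1 <- k1$bbox; b2 <- k2$bbox
  r0 <- max(b1[1], b2[1]) - 1L; r1 <- min(b1[2], b2[2]) + 1L
  c0 <- max(b1[3], b2[3]) - 1L; c1 <- min(b1[4], b2[4]) + 1L
  if (r0 > r1 || c0 > c1) return(FALSE)
  g1 <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
  g2 <- g1
  paste_crop <- function(g, k) {
    rlo <- max(k$bbox[1], r0); rhi <- min(k$bbox[2], r1)
    clo <- max(k$bbox[3], c0); chi <- min(k$bbox[4], c1)
    if (rlo > rhi || clo > chi) return(g)
    rr <- rlo:rhi
    cc <- clo:chi
    g[rr - r0 + 1L, cc - c0 + 1L] <-
      k$mask[rr - k$bbox[1] + 1L, cc - k$bbox[3] + 1L, drop = FALSE] * 1L
    g
  }
  g1 <- paste_crop(g1, k1)
  g2 <- paste_crop(g2, k2)
  any(dilate(g1, se_box(3L)) & g2)
}

#' Generate a synthetic adhered-kernel scene with ground truth
#'
#' Places `n_kernels` random ellipses: with probability
#' `adhesion_probability` a kernel is placed against a randomly chosen
#' existing kernel with a target overlap drawn up to `overlap_cap` of the
#' smaller kernel's area (at least one shared pixel); otherwise it is placed
#' clear of all existing kernels. A `damage_fraction` of kernels then loses a
#' concave boundary bite whose maximum inward depth is drawn from
#' `bite_depth_range` (bites are curvature-compensated so the drawn depth is
#' what a convexity-defect detector measures). The clean scene is rendered in
#' colour, then the illumination ramp and speckles are applied. Deterministic
#' for a fixed `rng_seed`.
#'
#' @param spec a [scene_spec()].
#' @return object of class `maize_scene`: list with `image`
#'   (`height x width x 3` integer array), `truth` (class `scene_truth`:
#'   `masks` as bbox-cropped logical matrices, `damage_labels`,
#'   `cluster_ids`, `true_count`), `clean_mask` (0/1 foreground of the
#'   pre-noise scene) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$rng_seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  h <- spec$image_height
  w <- spec$image_width
  kernels <- vector("list", spec$n_kernels)
  for (k in seq_len(spec$n_kernels)) {
    ax <- sort(runif(2, spec$kernel_axis_range[1], spec$kernel_axis_range[2]))
    a <- ax[2]; b <- ax[1]
    theta <- runif(1, 0, pi)
    level <- runif(1, spec$kernel_level_range[1], spec$kernel_level_range[2])
    adhere <- k > 1L && runif(1) < spec$adhesion_probability
    placed <- place_kernel(kernels[seq_len(k - 1L)], a, b, theta, adhere, spec)
    if (is.null(placed)) {
      stop(errorCondition(
        sprintf("could not place kernel %d of %d: image too small or too crowded",
                k, spec$n_kernels),
        class = c("maizeseg_capacity_error", "error", "condition")
      ))
    }
    placed$a <- a; placed$b <- b; placed$theta <- theta; placed$level <- level
    kernels[[k]] <- placed
  }
  # damage bites
  n_dam <- round(spec$damage_fraction * spec$n_kernels)
  dam_idx <- if (n_dam > 0) sort(sample(spec$n_kernels, n_dam)) else integer(0)
  labels <- rep("intact", spec$n_kernels)
  for (k in dam_idx) {
    kernels[[k]] <- apply_bite(kernels[[k]], spec, h, w)
    labels[k] <- "damaged"
  }
  # adhesion clusters (union-find over touching pairs)
  parent <- seq_len(spec$n_kernels)
  findp <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(spec$n_kernels)) {
    for (j in seq_len(i - 1L)) {
      if (bbox_near(kernels[[i]]$bbox, kernels[[j]]$bbox, 2L) &&
          crops_touch(kernels[[i]], kernels[[j]])) {
        parent[findp(i)] <- findp(j)
      }
    }
  }
  cluster_ids <- vapply(seq_len(spec$n_kernels), findp, integer(1))
  cluster_ids <- match(cluster_ids, unique(cluster_ids))
  # render
  clean_mask <- matrix(0L, h, w)
  gray <- matrix(spec$background_level, h, w)
  for (k in seq_len(spec$n_kernels)) {
    kk <- kernels[[k]]
    bb <- kk$bbox
    blk <- gray[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    blk[kk$mask] <- kk$level
    gray[bb[1]:bb[2], bb[3]:bb[4]] <- blk
    fg <- clean_mask[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    fg[kk$mask] <- 1L
    clean_mask[bb[1]:bb[2], bb[3]:bb[4]] <- fg
  }
  # colour: kernel-coloured pixels keep the same luma as the gray render
  cw <- c(1, 0.82, 0.35)
  cw <- cw / sum(cw * c(0.299, 0.587, 0.114))
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    m <- gray
    sel <- clean_mask == 1L
    m[sel] <- gray[sel] * cw[ch]
    m[!sel] <- spec$background_level
    img[, , ch] <- m
  }
  # illumination ramp (horizontal), then speckles
  ramp <- spec$illumination_slope * (matrix(seq_len(w), h, w, byrow = TRUE) - (w + 1) / 2)
  for (ch in 1:3) img[, , ch] <- img[, , ch] + ramp
  n_spk <- round(spec$speckle_density * h * w)
  if (n_spk > 0) {
    idx <- sample(h * w, n_spk)
    n_salt <- round(0.8 * n_spk)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx[seq_len(n_salt)]] <- 255
      if (n_spk > n_salt) plane[idx[(n_salt + 1L):n_spk]] <- 0
      img[, , ch] <- plane
    }
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  storage.mode(img) <- "integer"
  truth <- structure(
    list(
      masks = lapply(kernels, function(kk) list(bbox = kk$bbox, mask = kk$mask)),
      damage_labels = labels,
      cluster_ids = cluster_ids,
      true_count = spec$n_kernels
    ),
    class = "scene_truth"
  )
  structure(
    list(image = img, truth = truth, clean_mask = clean_mask, spec = spec),
    class = "maize_scene"
  )
}

bbox_near <- function(b1, b2, gap) {
  b1[1] <= b2[2] + gap && b2[1] <= b1[2] + gap &&
    b1[3] <= b2[4] + gap && b2[3] <= b1[4] + gap
}

# find an admissible centre for a new kernel; returns list(cr, cc, bbox, mask)
# or NULL after exhausting the attempt budget
place_kernel <- function(existing, a, b, theta, adhere, spec) {
  h <- spec$image_height
  w <- spec$image_width
  ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  if (2 * ex + 4 > w || 2 * ey + 4 > h) return(NULL)
  n_exist <- length(existing)
  for (attempt in seq_len(200L)) {
    if (adhere && n_exist > 0L) {
      j <- sample.int(n_exist, 1L)
      partner <- existing[[j]]
      phi <- runif(1, 0, 2 * pi)
      target_frac <- runif(1, 0.02, max(0.05, spec$overlap_cap))
      cand <- place_adhered(partner, a, b, theta, phi, target_frac, h, w)
    } else {
      cr <- runif(1, ey + 2, h - ey - 1)
      cc <- runif(1, ex + 2, w - ex - 1)
      cand <- list(cr = cr, cc = cc)
    }
    if (is.null(cand)) next
    if (cand$cr < ey + 2 || cand$cr > h - ey - 1 ||
        cand$cc < ex + 2 || cand$cc > w - ex - 1) next
    re <- rasterize_ellipse(cand$cr, cand$cc, a, b, theta, h, w)
    if (is.null(re)) next
    area_new <- sum(re$mask)
    ok <- TRUE
    for (i in seq_len(n_exist)) {
      other <- existing[[i]]
      if (!bbox_near(re$bbox, other$bbox, 3L)) next
      ov <- crop_overlap(re, other)
      if (adhere && i == j) {
        # partner overlap already tuned by place_adhered
        if (ov < 1L || ov > spec$overlap_cap * min(area_new, sum(other$mask))) {
          ok <- FALSE
          break
        }
      } else if (adhere) {
        # incidental contact with a third kernel is allowed within the cap
        if (ov > spec$overlap_cap * min(area_new, sum(other$mask))) {
          ok <- FALSE
          break
        }
      } else {
        # isolated placement: keep clear of everything (small gap)
        re2 <- rasterize_ellipse(cand$cr, cand$cc, a + 2, b + 2, theta, h, w)
        if (crop_overlap(re2, other) > 0L) {
          ok <- FALSE
        }
        if (!ok) break
      }
    }
    if (ok && adhere && n_exist > 0L) {
      if (crop_overlap(re, existing[[j]]) < 1L) ok <- FALSE
    }
    if (ok) {
      return(list(cr = cand$cr, cc = cand$cc, bbox = re$bbox, mask = re$mask))
    }
  }
  NULL
}

# bisect the centre distance along direction phi from the partner so that the
# pixel overlap hits target_frac of the smaller kernel's area
place_adhered <- function(partner, a, b, theta, phi, target_frac, h, w) {
  dirv <- c(sin(phi), cos(phi)) # (row, col) step
  smax <- partner$a + a + 2
  area_p <- sum(partner$mask)
  overlap_at <- function(s) {
    cr <- partner$cr + s * dirv[1]
    cc <- partner$cc + s * dirv[2]
    re <- rasterize_ellipse(cr, cc, a, b, theta, h, w)
    if (is.null(re)) return(list(ov = 0L, cr = cr, cc = cc))
    list(ov = crop_overlap(re, partner), cr = cr, cc = cc, area = sum(re$mask))
  }
  probe <- overlap_at(0.35 * smax)
  amin <- min(area_p, probe$area %||% area_p)
  target <- max(1, target_frac * amin)
  lo <- 0.2 * smax # deep overlap
  hi <- smax       # clear
  for (it in 1:14) {
    mid <- (lo + hi) / 2
    o <- overlap_at(mid)
    if (o$ov > target) lo <- mid else hi <- mid
  }
  o <- overlap_at(lo)
  if (o$ov < 1L) return(NULL)
  list(cr = o$cr, cc = o$cc)
}

# subtract a curvature-compensated elliptical bite from a kernel mask
apply_bite <- function(kk, spec, h, w) {
  for (attempt in 1:10) {
    side <- sample(c(pi / 2, 3 * pi / 2), 1L)
    t <- side + runif(1, -0.35, 0.35)
    # boundary point and local frame (x = col, y = row)
    ca <- cos(kk$theta); sa <- sin(kk$theta)
    px <- kk$a * cos(t); py <- kk$b * sin(t)
    bx <- kk$cc + px * ca - py * sa
    by <- kk$cr + px * sa + py * ca
    tx <- -kk$a * sin(t); ty <- kk$b * cos(t)
    bite_theta <- atan2(tx * sa + ty * ca, tx * ca - ty * sa)
    r_loc <- (kk$a^2 * sin(t)^2 + kk$b^2 * cos(t)^2)^1.5 / (kk$a * kk$b)
    depth <- runif(1, spec$bite_depth_range[1], spec$bite_depth_range[2])
    # long flank bite: mouth runs along the major axis, so the distance-ridge
    # of the bitten kernel stays single-peaked (no spurious watershed split)
    mouth <- runif(1, 0.65, 0.85) * kk$a
    d_eff <- min(depth + mouth^2 / (2 * r_loc) + 1, 1.15 * kk$b)
    bite <- rasterize_ellipse(by, bx, mouth, d_eff, bite_theta, h, w)
    if (is.null(bite)) next
    new_mask <- kk$mask
    bb <- kk$bbox
    r0 <- max(bb[1], bite$bbox[1]); r1 <- min(bb[2], bite$bbox[2])
    c0 <- max(bb[3], bite$bbox[3]); c1 <- min(bb[4], bite$bbox[4])
    if (r0 > r1 || c0 > c1) next
    sub_b <- bite$mask[(r0:r1) - bite$bbox[1] + 1L, (c0:c1) - bite$bbox[3] + 1L, drop = FALSE]
    sub_k <- new_mask[(r0:r1) - bb[1] + 1L, (c0:c1) - bb[3] + 1L, drop = FALSE]
    sub_k[sub_b] <- FALSE
    new_mask[(r0:r1) - bb[1] + 1L, (c0:c1) - bb[3] + 1L] <- sub_k
    if (sum(new_mask) < 0.4 * sum(kk$mask)) next
    comp <- cpp_label_components(new_mask * 1L, 8L)
    if (attr(comp, "n_labels") != 1L) next
    kk$mask <- new_mask
    return(kk)
  }
  kk # give up: kernel stays intact-shaped (caller still labels it damaged)
}

#' Build full-frame rasters from scene ground truth
#'
#' `truth_foreground()` returns the union of the instance masks as a 0/1
#' matrix; `truth_label_map()` an instance label map (overlapping pixels take
#' the lower kernel id).
#'
#' @param truth a `scene_truth`.
#' @param dim `c(height, width)` of the frame.
#' @return integer matrix.
#' @export
truth_foreground <- function(truth, dim) {
  out <- matrix(0L, dim[1], dim[2])
  for (m in truth$masks) {
    bb <- m$bbox
    blk <- out[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    blk[m$mask] <- 1L
    out[bb[1]:bb[2], bb[3]:bb[4]] <- blk
  }
  out
}

#' @rdname truth_foreground
#' @export
truth_label_map <- function(truth, dim) {
  out <- matrix(0L, dim[1], dim[2])
  for (k in rev(seq_along(truth$masks))) {
    m <- truth$masks[[k]]
    bb <- m$bbox
    blk <- out[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    blk[m$mask] <- k
    out[bb[1]:bb[2], bb[3]:bb[4]] <- blk
  }
  out
}

#' Per-kernel features from ground-truth masks
#'
#' Traces each ground-truth kernel mask and computes its eight shape
#' descriptors; used to build classifier training tables without running the
#' segmentation pipeline.
#'
#' @param scene a `maize_scene`.
#' @return data frame of kernel records (see [extract_features()]) with the
#'   true damage labels.
#' @export
scene_truth_features <- function(scene) {
  truth <- scene$truth
  contours <- lapply(seq_along(truth$masks), function(k) {
    m <- truth$masks[[k]]
    crop <- matrix(0L, nrow(m$mask) + 2L, ncol(m$mask) + 2L)
    crop[2:(nrow(m$mask) + 1L), 2:(ncol(m$mask) + 1L)] <- m$mask * 1L
    ct <- orient_ccw(cpp_trace_boundary(crop, 1L))
    attr(ct, "area") <- sum(m$mask)
    attr(ct, "id") <- k
    ct
  })
  extract_features(contours, labels = truth$damage_labels)
}

#' Generate a per-kernel feature dataset with an image-level split
#'
#' Generates every scene in `spec_list`, computes ground-truth kernel
#' features and assigns whole scenes (never individual kernels) to the
#' training or test split -- no leakage between splits. Deterministic for
#' fixed specs and `rng_seed`.
#'
#' @param spec_list list of [scene_spec()] objects.
#' @param split_fraction fraction of scenes assigned to training, in (0, 1).
#' @param rng_seed seed for the split assignment.
#' @return list with data frames `train` and `test` (feature records plus a
#'   `scene` column) and the scene index vectors `train_scenes`,
#'   `test_scenes`.
#' @export
generate_feature_dataset <- function(spec_list, split_fraction = 0.8,
                                     rng_seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie in (0, 1)")
  }
  n <- length(spec_list)
  n_train <- round(split_fraction * n)
  if (n_train < 1L || n_train >= n) {
    stop("split leaves an empty training or test set")
  }
  ord <- with_seed(rng_seed, sample.int(n))
  train_scenes <- sort(ord[seq_len(n_train)])
  test_scenes <- sort(ord[(n_train + 1L):n])
  tables <- lapply(seq_len(n), function(i) {
    df <- scene_truth_features(generate_scene(spec_list[[i]]))
    if (nrow(df)) df$scene <- i
    df
  })
  bind <- function(ids) {
    out <- do.call(rbind, tables[ids])
    rownames(out) <- NULL
    out
  }
  list(
    train = bind(train_scenes), test = bind(test_scenes),
    train_scenes = train_scenes, test_scenes = test_scenes
  )
}
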