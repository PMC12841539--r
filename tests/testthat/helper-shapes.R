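# shared fixtures: digital shapes, tiny scene specs, and independent oracles

disk_mask <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad
  cc <- r + pad
  idx <- as.matrix(expand.grid(seq_len(n), seq_len(n)))
  m <- matrix(0L, n, n)
  m[idx[(idx[, 1] - cc)^2 + (idx[, 2] - cc)^2 <= r^2, , drop = FALSE]] <- 1L
  m
}

# mask with k disks of radius r at the given (row, col) centres
disks_mask <- function(centres, r, h, w) {
  idx <- as.matrix(expand.grid(seq_len(h), seq_len(w)))
  m <- matrix(0L, h, w)
  for (i in seq_len(nrow(centres))) {
    sel <- (idx[, 1] - centres[i, 1])^2 + (idx[, 2] - centres[i, 2])^2 <= r^2
    m[idx[sel, , drop = FALSE]] <- 1L
  }
  m
}

ellipse_mask_at <- function(h, w, cr, cc, a, b, theta = 0) {
  idx <- as.matrix(expand.grid(seq_len(h), seq_len(w)))
  dy <- idx[, 1] - cr
  dx <- idx[, 2] - cc
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  m <- matrix(0L, h, w)
  m[idx[u^2 + v^2 <= 1, , drop = FALSE]] <- 1L
  m
}

# small-scene spec used across tests (fast to generate)
small_scene_spec <- function(seed, n_kernels = 12L, width = 700L, height = 520L,
                             adhesion_probability = 0.5, damage_fraction = 0.3,
                             overlap_cap = 0.3, ...) {
  scene_spec(
    image_width = width, image_height = height, n_kernels = n_kernels,
    adhesion_probability = adhesion_probability,
    damage_fraction = damage_fraction, overlap_cap = overlap_cap,
    rng_seed = seed, ...
  )
}

# --- independent oracles -----------------------------------------------------

# Otsu by explicit per-threshold class statistics (O(L * L) brute force)
otsu_bruteforce <- function(img) {
  v <- as.vector(img)
  best_t <- 0L
  best_s <- -1
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) s <- 0 else {
      w1 <- length(lo) / length(v)
      w2 <- 1 - w1
      mu <- mean(v)
      s <- w1 * (mean(lo) - mu)^2 + w2 * (mean(hi) - mu)^2
    }
    if (s > best_s + 1e-12) {
      best_s <- s
      best_t <- t
    }
  }
  best_t
}

# exact EDT by direct minimisation over all background pixels
edt_bruteforce <- function(mask) {
  bg <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  fg <- which(mask == 1, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# point-to-infinite-line distance via projection (independent of the
# cross-product formula)
point_line_dist <- function(a, b, c0) {
  ab <- b - a
  ac <- c0 - a
  proj <- sum(ac * ab) / sum(ab * ab)
  sqrt(sum((ac - proj * ab)^2))
}
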