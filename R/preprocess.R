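#' Convert an RGB image to grayscale
#'
#' Uses the luma weighting `Gray = 0.299 R + 0.587 G + 0.114 B`, rounded
#' half-up to the nearest integer and clipped to `[0, 255]`. Single-channel
#' input is passed through unchanged with a warning.
#'
#' @param img 3-channel raster image (see [as_raster()]).
#' @return single-channel integer matrix.
#' @export
#' @examples
#' img <- array(c(255, 0, 0), c(1, 1, 3))
#' to_grayscale(img) # 76
to_grayscale <- function(img) {
  img <- as_raster(img)
  if (n_channels(img) == 1L) {
    warning("image is already single-channel; returning it unchanged")
    return(img)
  }
  g <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  g <- floor(g + 0.5) # round half-up
  g[g < 0] <- 0
  g[g > 255] <- 255
  dim(g) <- dim(img)[1:2]
  storage.mode(g) <- "integer"
  g
}

#' Otsu's threshold by maximum inter-class variance
#'
#' Exhaustively evaluates every threshold `t` in `[0, L-1]` (L = 256 gray
#' levels), splitting the histogram into a low class `[0, t]` and a high class
#' `[t+1, L-1]`, and returns the `t` maximising the inter-class variance
#' \deqn{\sigma_B^2(t) = \omega_1(\mu_1-\mu)^2 + \omega_2(\mu_2-\mu)^2.}
#' Ties are broken by the smallest `t`.
#'
#' @param img single-channel raster image.
#' @return a list of class `otsu_threshold` with elements `t_optimal`, and the
#'   full histogram statistics: `p` (per-level probability), `omega1`,
#'   `omega2`, `mu1`, `mu2` (per-threshold class probabilities and means),
#'   `mu` (global mean) and `sigma_b2` (inter-class variance per threshold).
#' @export
otsu_threshold <- function(img) {
  img <- as_raster(img)
  if (n_channels(img) != 1L) stop("otsu_threshold() expects a grayscale image")
  L <- 256L
  counts <- tabulate(as.vector(img) + 1L, nbins = L)
  if (sum(counts > 0L) < 2L) {
    stop("degenerate histogram: image has fewer than 2 distinct gray levels")
  }
  p <- counts / sum(counts)
  lev <- 0:(L - 1L)
  omega1 <- cumsum(p)
  omega2 <- 1 - omega1
  cmean <- cumsum(lev * p)
  mu <- cmean[L]
  mu1 <- ifelse(omega1 > 0, cmean / omega1, 0)
  mu2 <- ifelse(omega2 > 0, (mu - cmean) / omega2, 0)
  sigma_b2 <- omega1 * (mu1 - mu)^2 + omega2 * (mu2 - mu)^2
  t_optimal <- lev[which.max(sigma_b2)] # which.max takes the first maximum
  structure(
    list(
      t_optimal = t_optimal, p = p, omega1 = omega1, omega2 = omega2,
      mu1 = mu1, mu2 = mu2, mu = mu, sigma_b2 = sigma_b2
    ),
    class = "otsu_threshold"
  )
}

#' Threshold a grayscale image into a binary mask
#'
#' Pixels strictly above `t` become foreground (1) by default -- bright
#' kernels on a dark matte background. Set `polarity = "dark"` for scenes
#' with dark objects on a bright background.
#'
#' @param img single-channel raster image.
#' @param t threshold in `[0, 255]` (a bare number or an [otsu_threshold()]
#'   result).
#' @param polarity `"bright"` (default) or `"dark"` foreground.
#' @return integer 0/1 matrix of the same size.
#' @export
binarize <- function(img, t, polarity = c("bright", "dark")) {
  img <- as_raster(img)
  polarity <- match.arg(polarity)
  if (inherits(t, "otsu_threshold")) t <- t$t_optimal
  if (t < 0 || t > 255) stop("threshold must lie in [0, 255]")
  mask <- if (polarity == "bright") img > t else img <= t
  mask <- mask * 1L
  storage.mode(mask) <- "integer"
  mask
}

#' Structuring elements for binary morphology
#'
#' A structuring element is a logical matrix plus an anchor (its origin),
#' 1-based. `se_box()` is the full n x n square, `se_cross()` the axial
#' cross, `se_disc()` a digital disk of the given radius.
#'
#' @param n odd side length.
#' @param r disk radius in pixels.
#' @param shape logical matrix.
#' @param anchor `c(row, col)` origin, defaults to the centre.
#' @return an object of class `struct_elem`.
#' @export
struct_elem <- function(shape, anchor = NULL) {
  shape <- shape != 0
  if (!any(shape)) stop("structuring element must contain at least one set pixel")
  if (is.null(anchor)) anchor <- c((nrow(shape) + 1L) %/% 2L, (ncol(shape) + 1L) %/% 2L)
  if (anchor[1] < 1 || anchor[1] > nrow(shape) || anchor[2] < 1 || anchor[2] > ncol(shape)) {
    stop("anchor must lie inside the structuring element")
  }
  structure(list(shape = shape, anchor = as.integer(anchor)), class = "struct_elem")
}

#' @rdname struct_elem
#' @export
se_box <- function(n = 3L) struct_elem(matrix(TRUE, n, n))

#' @rdname struct_elem
#' @export
se_cross <- function(n = 3L) {
  m <- matrix(FALSE, n, n)
  mid <- (n + 1L) %/% 2L
  m[mid, ] <- TRUE
  m[, mid] <- TRUE
  struct_elem(m)
}

#' @rdname struct_elem
#' @export
se_disc <- function(r) {
  d <- 2L * as.integer(r) + 1L
  cc <- r + 1
  idx <- expand.grid(i = seq_len(d), j = seq_len(d))
  m <- matrix((idx$i - cc)^2 + (idx$j - cc)^2 <= r^2, d, d)
  struct_elem(m)
}

# relative offsets (dr, dc) of the set pixels of a structuring element
se_offsets <- function(se) {
  w <- which(se$shape, arr.ind = TRUE)
  cbind(w[, 1] - se$anchor[1], w[, 2] - se$anchor[2])
}

#' Reflect a structuring element about its origin
#' @param se a [struct_elem()].
#' @return the reflected `struct_elem`.
#' @export
se_reflect <- function(se) {
  shape <- se$shape[rev(seq_len(nrow(se$shape))), rev(seq_len(ncol(se$shape))), drop = FALSE]
  anchor <- c(nrow(se$shape) + 1L - se$anchor[1], ncol(se$shape) + 1L - se$anchor[2])
  struct_elem(shape, anchor)
}

#' Binary morphology: erosion, dilation, opening, closing
#'
#' Set-theoretic morphology on 0/1 masks. Erosion keeps the pixels `z` whose
#' translated structuring element fits inside the foreground
#' (`A erode B = {z : B_z subset A}`); dilation keeps the pixels whose
#' reflected element hits the foreground. Opening is erosion-then-dilation
#' (removes speckles smaller than the element); closing is the reverse (fills
#' comparable holes). Pixels outside the image are background.
#'
#' @param mask integer/logical 0-1 matrix.
#' @param se a [struct_elem()]; defaults to the 3x3 cross.
#' @return integer 0/1 matrix.
#' @export
erode <- function(mask, se = se_cross(3L)) {
  mask <- (mask != 0) * 1L
  off <- se_offsets(se)
  out <- matrix(1L, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    # containment: A must be set at z + b  =>  test shift of A by -b
    out <- out & shift_matrix(mask, -off[k, 1], -off[k, 2], fill = 0L)
  }
  out * 1L
}

#' @rdname erode
#' @export
dilate <- function(mask, se = se_cross(3L)) {
  mask <- (mask != 0) * 1L
  off <- se_offsets(se)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    # hit: exists b in B with z - b in A  =>  union of shifts of A by +b
    out <- out | shift_matrix(mask, off[k, 1], off[k, 2], fill = 0L)
  }
  out * 1L
}

#' @rdname erode
#' @export
opening <- function(mask, se = se_cross(3L)) dilate(erode(mask, se), se)

#' @rdname erode
#' @export
closing <- function(mask, se = se_cross(3L)) erode(dilate(mask, se), se)

#' Full preprocessing stage: grayscale, Otsu, morphological cleanup
#'
#' @param img raster image (RGB or grayscale).
#' @param se structuring element for the opening/closing pass.
#' @param morphology apply the opening-then-closing cleanup (default TRUE).
#' @param polarity foreground polarity, see [binarize()].
#' @return list with `gray`, `threshold` (the [otsu_threshold()] result) and
#'   `mask` (cleaned binary mask).
#' @export
preprocess_image <- function(img, se = se_cross(3L), morphology = TRUE,
                             polarity = "bright") {
  gray <- if (n_channels(as_raster(img)) == 3L) to_grayscale(img) else as_raster(img)
  th <- otsu_threshold(gray)
  mask <- binarize(gray, th, polarity = polarity)
  if (morphology) mask <- closing(opening(mask, se), se)
  list(gray = gray, threshold = th, mask = mask)
}
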