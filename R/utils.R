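#' Run code with a private, seeded RNG stream
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so package functions are reproducible without
#' clobbering the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# shift a matrix by (dr, dc), padding with `fill`; positive dr moves content
# down (i.e. out(i,j) = m(i - dr, j - dc))
shift_matrix <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (1L + dr > nr || nr + dr < 1L || 1L + dc > nc || nc + dc < 1L) return(out)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

# truncate towards zero at `digits` decimals -- the display convention used by
# the shape-feature reference table this package reproduces
trunc_digits <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
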