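# Internal helpers shared across modules: argument checks, scoped RNG,
# separable Gaussian filtering with replicate boundaries.

stop_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(..., call. = call.)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' @noRd
check_scalar <- function(x, name, lower = -Inf, integerish = FALSE) {
  stop_if(!is_scalar_number(x), sprintf("`%s` must be a single finite number", name))
  stop_if(x < lower, sprintf("`%s` must be >= %s", name, format(lower)))
  if (integerish) {
    stop_if(abs(x - round(x)) > 1e-8, sprintf("`%s` must be an integer", name))
  }
  invisible(x)
}

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Discrete Gaussian taps at integer offsets -r..r: the Gaussian integrated
# over unit pixel bins (erf differences), normalised to sum 1. Unlike point
# sampling, this keeps sub-pixel sigmas strictly non-trivial, so slightly
# defocused planes remain distinguishable from the in-focus one.
gaussian_taps <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- seq(-radius, radius)
  v <- stats::pnorm((k + 0.5) / sigma) - stats::pnorm((k - 0.5) / sigma)
  v / sum(v)
}

# 1-D convolution of the rows (axis = 1) or columns (axis = 2) of a matrix
# with replicate (edge-clamp) padding, implemented as a shift-and-add over
# the kernel taps; fast for the short kernels used here.
conv_axis_replicate <- function(x, taps, axis) {
  n <- length(taps)
  if (n == 1L) return(x * taps)
  r <- (n - 1L) %/% 2L
  d <- dim(x)[axis]
  out <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(n)) {
    off <- j - r - 1L          # offset of this tap
    idx <- pmin(pmax(seq_len(d) + off, 1L), d)
    out <- out + taps[j] * (if (axis == 1L) x[idx, , drop = FALSE]
                            else x[, idx, drop = FALSE])
  }
  out
}

# Separable Gaussian blur of a matrix (replicate boundary). sigma in px.
gaussian_blur_matrix <- function(x, sigma) {
  if (sigma <= 0) return(x)
  taps <- gaussian_taps(sigma)
  conv_axis_replicate(conv_axis_replicate(x, taps, 1L), taps, 2L)
}

# Apply a matrix -> matrix function to every channel of an image (matrix or
# h x w x 3 array), preserving shape.
map_channels <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- f(img[, , ch])
  out
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)
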