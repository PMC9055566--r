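# Shared fixtures and independent oracles, all generated in code.

rmse <- function(x, y) sqrt(mean((x - y)^2))

# seeded random texture matrix on [lo, hi]
rand_texture <- function(h, w, seed, lo = 20, hi = 235) {
  set.seed(seed)
  matrix(runif(h * w, lo, hi), h, w)
}

# seeded random RGB image
rand_rgb <- function(h, w, seed, lo = 0, hi = 255) {
  set.seed(seed)
  array(runif(h * w * 3, lo, hi), c(h, w, 3))
}

# separable Gaussian blur reference, reusing only base R (independent of
# package internals): pixel-integrated taps, replicate padding, double loop.
ref_gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- seq(-r, r)
  taps <- pnorm((k + 0.5) / sigma) - pnorm((k - 0.5) / sigma)
  taps <- taps / sum(taps)
  h <- nrow(x); w <- ncol(x)
  tmp <- matrix(0, h, w)
  for (i in seq_len(h)) {
    idx <- pmin(pmax(i + k, 1L), h)
    tmp[i, ] <- colSums(x[idx, , drop = FALSE] * taps)
  }
  out <- matrix(0, h, w)
  for (j in seq_len(w)) {
    idx <- pmin(pmax(j + k, 1L), w)
    out[, j] <- colSums(t(tmp[, idx, drop = FALSE]) * taps)
  }
  out
}

# double-loop 4-neighbour |Laplacian| oracle with replicate padding
brute_abs_laplacian <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  cl <- function(i, n) min(max(i, 1L), n)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    out[i, j] <- abs(img[cl(i - 1L, h), j] + img[cl(i + 1L, h), j] +
                     img[i, cl(j - 1L, w)] + img[i, cl(j + 1L, w)] -
                     4 * img[i, j])
  }
  out
}

# wrapped 2-D Gaussian kernel oracle: direct double sum over wrap replicas
wrapped_gauss_kernel <- function(h, w, sigma) {
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- 0
    for (a in -3:3) for (b in -3:3) {
      v <- v + exp(-(((i - 1) + a * h)^2 + ((j - 1) + b * w)^2) / (2 * sigma^2))
    }
    out[i, j] <- v
  }
  out / sum(out)
}

# exact sign-test p oracle by full 2^n outcome enumeration
enum_sign_p <- function(wins_a, wins_b) {
  n <- wins_a + wins_b
  k <- max(wins_a, wins_b)
  outcomes <- expand.grid(rep(list(0:1), n))
  succ <- rowSums(outcomes)
  min(1, 2 * mean(succ >= k))
}

# constant-depth synthetic scene focused at plane k (1-based) of n_planes
const_depth_scene <- function(k, n_planes = 15, h = 128, w = 128, seed = 1) {
  sc <- generate_scene(h, w, seed = seed)
  sc$depth[] <- (k - 1) / (n_planes - 1)
  sc
}

# small default parameter sets that keep module tests fast
small_fba <- function(tile_size = 64, stride = 32, ...) {
  fba_params(tile_size = tile_size, stride = stride, ...)
}
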