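test_that("smooth_magnitude: no-op, constant preservation, impulse kernel", {
  mag <- abs(rand_texture(8, 8, seed = 1))
  expect_identical(smooth_magnitude(mag, 0), mag)
  # constants pass through any sigma (kernel sums to 1)
  expect_equal(smooth_magnitude(matrix(3.5, 8, 8), 2), matrix(3.5, 8, 8),
               tolerance = 1e-12)
  # unit impulse at bin (1,1): response is the wrapped 2-D Gaussian kernel
  imp <- matrix(0, 8, 8); imp[1, 1] <- 1
  expect_equal(smooth_magnitude(imp, 1), wrapped_gauss_kernel(8, 8, 1),
               tolerance = 1e-10)
  expect_equal(sum(smooth_magnitude(imp, 1)), 1, tolerance = 1e-12)
  expect_error(smooth_magnitude(mag, -1), "mag_sigma")
})

test_that("fourier_weights matches the closed form and normalises", {
  # hand-evaluated two-frame bins
  m <- array(c(2, 1), c(1, 1, 2))
  expect_equal(as.vector(fourier_weights(m, 1)), c(2, 1) / 3, tolerance = 1e-12)
  expect_equal(as.vector(fourier_weights(m, 2)), c(4, 1) / 5, tolerance = 1e-12)
  # p = 0 gives uniform weights; n = 1 gives weight 1
  m4 <- array(abs(rnorm(6 * 5 * 4)) , c(6, 5, 4))
  expect_true(all(abs(fourier_weights(m4, 0) - 0.25) < 1e-12))
  expect_true(all(fourier_weights(array(runif(12), c(3, 4, 1)), 7) == 1))
  # zero-magnitude bins fall back to 1/n
  mz <- array(0, c(2, 2, 3)); mz[1, 1, ] <- c(1, 2, 3)
  wz <- fourier_weights(mz, 2)
  expect_equal(wz[2, 2, ], rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(fourier_weights(m4, -0.5), "p")
})

test_that("weights sum to 1 at every bin for all p, including extreme p", {
  set.seed(42)
  for (p in c(0, 1, 11, 100)) {
    mags <- array(runif(16 * 16 * 7, 0, 1e5), c(16, 16, 7))
    mags[1:2, 1:2, ] <- 0  # degenerate bins
    w <- fourier_weights(mags, p)
    sums <- apply(w, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
    expect_gte(min(w), 0)
  }
})

test_that("fba_merge: identity on duplicate bursts and p=0 mean equivalence", {
  f <- rand_texture(32, 32, seed = 9)
  for (k in c(1, 2, 7)) {
    out <- fba_merge(rep(list(f), k), fba_params(sharpen = FALSE))
    expect_lt(max(abs(out - f)), 1e-6)
  }
  # RGB identity too
  a <- rand_rgb(16, 16, seed = 10, lo = 10, hi = 245)
  expect_lt(max(abs(fba_merge(rep(list(a), 3), fba_params()) - a)), 1e-6)
  # p = 0: uniform weights make the merge a pixelwise arithmetic mean
  g <- rand_texture(32, 32, seed = 12)
  h <- rand_texture(32, 32, seed = 13)
  out0 <- fba_merge(list(f, g, h), fba_params(p = 0))
  expect_lt(max(abs(out0 - (f + g + h) / 3)), 1e-6)
})

test_that("fba_merge prefers the sharp frame of a sharp/blurred pair", {
  sharp <- ref_gaussian_blur(rand_texture(64, 64, seed = 20), 0.6) # band-limit
  blurred <- ref_gaussian_blur(sharp, 3)
  out <- fba_merge(list(sharp, blurred), fba_params(p = 15, mag_sigma = 2))
  expect_lt(rmse(out, sharp), rmse(out, blurred))
})

test_that("large p approaches the per-bin argmax reconstruction", {
  # two frames whose smoothed magnitudes are strictly ordered at every bin:
  # the argmax reconstruction is then frame 1 itself
  f1 <- rand_texture(32, 32, seed = 30, lo = 50, hi = 200)
  f2 <- 0.5 * f1
  errs <- vapply(c(1, 10, 100), function(p) {
    rmse(fba_merge(list(f1, f2), fba_params(p = p)), f1)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  expect_lt(errs[3], 1e-3)
})

test_that("fba_merge conserves the common DC level", {
  f <- rand_texture(24, 24, seed = 31, lo = 60, hi = 190)
  g <- rand_texture(24, 24, seed = 32, lo = 60, hi = 190)
  g <- g - mean(g) + mean(f)  # equal frame means
  out <- fba_merge(list(f, g), fba_params(p = 11))
  expect_equal(mean(out), mean(f), tolerance = 1e-6)
})

test_that("fba_merge validates its inputs", {
  expect_error(fba_merge(list(), fba_params()), "nonempty")
  expect_error(fba_merge(list(matrix(0, 4, 4), matrix(0, 5, 4)), fba_params()),
               "identical dimensions")
  expect_error(fba_params(p = -1), "p")
  expect_error(fba_params(stride = 300, tile_size = 256), "stride")
})
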