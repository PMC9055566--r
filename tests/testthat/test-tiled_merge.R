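test_that("plan_tiles reproduces the stated origin rule", {
  # acquisition geometry: 960 x 1280, 256 px tiles, 128 px stride
  g <- plan_tiles(960, 1280, 256, 128)
  rows <- sort(unique(g$origins[, "row"]))
  cols <- sort(unique(g$origins[, "col"]))
  expect_identical(rows, c(seq(1L, 641L, 128L), 705L))   # clamped final row
  expect_identical(cols, seq(1L, 1025L, 128L))
  expect_identical(nrow(g$origins), 63L)
  # single-tile and clamped-final-origin cases
  expect_identical(unname(plan_tiles(256, 256, 256, 128)$origins),
                   cbind(1L, 1L))
  g2 <- plan_tiles(300, 300, 256, 128)
  expect_identical(sort(unique(g2$origins[, "row"])), c(1L, 45L))
  expect_identical(nrow(g2$origins), 4L)
  expect_error(plan_tiles(100, 100, 256, 128), "exceeds")
})

test_that("every pixel is covered by at least one tile (fuzzed geometries)", {
  set.seed(99)
  for (i in 1:100) {
    h <- sample(16:200, 1); w <- sample(16:200, 1)
    ts <- sample(2:min(h, w), 1); sd_ <- sample(seq_len(ts), 1)
    g <- plan_tiles(h, w, ts, sd_)
    expect_true(all(g$origins[, "row"] + ts - 1L <= h) &&
                all(g$origins[, "col"] + ts - 1L <= w))
    cov <- matrix(0L, h, w)
    for (t in seq_len(nrow(g$origins))) {
      r <- g$origins[t, "row"]; c <- g$origins[t, "col"]
      cov[r:(r + ts - 1L), c:(c + ts - 1L)] <- 1L
    }
    expect_identical(sum(cov), h * w)
    expect_false(any(duplicated(g$origins)))
  }
})

test_that("select_frame_window centres, clamps and honours foreground bias", {
  expect_identical(unname(select_frame_window(8, 15, 7)), c(5L, 11L))
  expect_identical(unname(select_frame_window(1, 15, 7)), c(1L, 7L))
  expect_identical(unname(select_frame_window(15, 15, 7)), c(9L, 15L))
  # short stacks shrink the window
  expect_identical(unname(select_frame_window(2, 4, 7)), c(1L, 4L))
  # foreground bias: window ends at the best frame, clamped at the start
  expect_identical(unname(select_frame_window(8, 15, 7, foreground_bias = TRUE)),
                   c(2L, 8L))
  expect_identical(unname(select_frame_window(3, 15, 7, foreground_bias = TRUE)),
                   c(1L, 7L))
  expect_error(select_frame_window(16, 15, 7), "out of range")
})

test_that("blend_weight_mask is a positive raised-cosine with exact 50% COLA", {
  for (n in c(4L, 64L, 256L)) {
    m <- blend_weight_mask(n)
    hann <- sin(pi * (seq_len(n) - 0.5) / n)^2
    expect_equal(m, outer(hann, hann), tolerance = 1e-12)
    expect_gt(min(m), 0)
    expect_identical(which(m == max(m), arr.ind = TRUE)[1, ] >= n / 2,
                     c(row = TRUE, col = TRUE))
    expect_equal(m, m[n:1, n:1], tolerance = 1e-12)          # 180-degree symmetry
    expect_equal(hann[seq_len(n / 2)] + hann[seq_len(n / 2) + n / 2],
                 rep(1, n / 2), tolerance = 1e-12)           # overlap-add
  }
})

test_that("focus_stack: identity, constants, and one-tile consistency", {
  f <- rand_rgb(96, 80, seed = 41, lo = 10, hi = 245)
  st <- focal_stack(rep(list(f), 7))
  res <- focus_stack(st, best_index = 4, params = small_fba())
  expect_lt(max(abs(res$image - f)), 1e-5)
  expect_identical(unname(res$frame_window), c(1L, 7L))
  # constant stacks return the constant (partition of unity)
  cst <- focal_stack(rep(list(array(123.4, c(70, 90, 3))), 5))
  out <- focus_stack(cst, best_index = 3, params = small_fba())
  expect_lt(max(abs(out$image - 123.4)), 1e-9)
  # image exactly one tile in size: tiled merge equals the global merge
  frames <- lapply(1:7, function(i) rand_rgb(64, 64, seed = 100 + i))
  st1 <- focal_stack(frames)
  tiled <- focus_stack(st1, best_index = 4, params = small_fba(stride = 64))
  direct <- fba_merge(frames, small_fba(stride = 64))
  expect_lt(max(abs(tiled$image - direct)), 1e-6)
})

test_that("focus_stack is deterministic and validates inputs", {
  sc <- generate_scene(96, 96, seed = 5)
  st <- render_focal_stack(sc, stack_params(n_planes = 9, seed = 5))
  p <- small_fba()
  r1 <- focus_stack(st, "auto", p)
  r2 <- focus_stack(st, "auto", p)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$best_index, r2$best_index)
  expect_error(focus_stack(st, best_index = 99, params = p), "out of range")
  expect_error(focal_stack(list()), "at least one frame")
})

test_that("merging a noiseless synthetic stack recovers sharpness and truth", {
  sc <- generate_scene(160, 128, seed = 1)
  st <- render_focal_stack(sc, stack_params(noise_sigma = 0, seed = 1))
  res <- focus_stack(st, "auto", small_fba())
  energies <- vapply(st$frames,
                     function(f) laplacian_energy(to_grayscale(f)), numeric(1))
  expect_gt(laplacian_energy(to_grayscale(res$image)), max(energies))
  best <- which.max(energies)
  expect_lt(rmse(res$image, sc$truth), rmse(st$frames[[best]], sc$truth))
})
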