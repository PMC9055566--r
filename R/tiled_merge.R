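#' Plan an overlapping tile grid
#'
#' Per axis the tile origins are `1, 1 + stride, 1 + 2*stride, ...` while
#' the tile still fits inside the image; if the last regular origin does not
#' reach `extent - tile_size + 1`, a final origin clamped to that position
#' is appended so every pixel is covered by a fully interior tile (no tile
#' ever extends past the image, and none is shrunk). At the gonioscopic
#' geometry (960 x 1280 px, 256 px tiles, 128 px stride) this yields
#' 7 x 9 = 63 tiles, the 960 axis getting a clamped final origin.
#'
#' @param image_height,image_width image extent, px.
#' @param tile_size square tile side, px.
#' @param stride shift between neighbouring tiles, px.
#' @return object of class `tile_grid`: list with `origins` (matrix with
#'   columns `row`, `col`, 1-based top-left corners, row-major order),
#'   `tile_size`, `stride`, `image_height`, `image_width`.
#' @export
plan_tiles <- function(image_height, image_width, tile_size = 256, stride = 128) {
  check_scalar(image_height, "image_height", 1, integerish = TRUE)
  check_scalar(image_width, "image_width", 1, integerish = TRUE)
  check_scalar(tile_size, "tile_size", 1, integerish = TRUE)
  check_scalar(stride, "stride", 1, integerish = TRUE)
  stop_if(stride > tile_size, "`stride` must not exceed `tile_size`")
  stop_if(tile_size > min(image_height, image_width),
          "tile_size exceeds the image extent")
  tile_size <- as.integer(tile_size); stride <- as.integer(stride)
  axis_origins <- function(extent) {
    last <- as.integer(extent) - tile_size + 1L
    o <- seq.int(1L, last, by = stride)
    if (o[length(o)] != last) o <- c(o, last)
    as.integer(o)
  }
  rows <- axis_origins(as.integer(image_height))
  cols <- axis_origins(as.integer(image_width))
  origins <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  structure(list(origins = origins, tile_size = as.integer(tile_size),
                 stride = as.integer(stride),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width)),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d tiles of %d px (stride %d) over %d x %d px\n",
              nrow(x$origins), x$tile_size, x$stride,
              x$image_height, x$image_width))
  invisible(x)
}

#' Choose the consecutive frame window around the best-focused frame
#'
#' Returns `min(window_size, stack_size)` consecutive 1-based frame indices
#' containing `best_index`. By default the window is centred on the best
#' frame (`floor(window/2)` frames before it) and shifted minimally to fit
#' the stack. With `foreground_bias = TRUE` the window instead ends at the
#' best frame, i.e. it is drawn from the foreground side (frame 1 is
#' nearest the gonio-prism), clamped likewise.
#'
#' @param best_index 1-based index of the best-focused frame.
#' @param stack_size number of frames in the stack.
#' @param window_size desired burst length (7 in the gonioscopic workflow).
#' @param foreground_bias logical; see above.
#' @return integer vector `c(first, last)` of 1-based inclusive indices.
#' @export
select_frame_window <- function(best_index, stack_size, window_size = 7,
                                foreground_bias = FALSE) {
  check_scalar(stack_size, "stack_size", 1, integerish = TRUE)
  check_scalar(window_size, "window_size", 1, integerish = TRUE)
  check_scalar(best_index, "best_index", 1, integerish = TRUE)
  stop_if(best_index > stack_size, "`best_index` is out of range")
  w <- min(as.integer(window_size), as.integer(stack_size))
  first <- if (foreground_bias) best_index - w + 1L else best_index - w %/% 2L
  first <- min(max(first, 1L), stack_size - w + 1L)
  c(first = as.integer(first), last = as.integer(first + w - 1L))
}

#' Raised-cosine blend mask for overlap-add tile synthesis
#'
#' A separable half-sample-shifted Hann window,
#' `h(i) = sin^2(pi * (i - 0.5) / N)` for `i = 1..N`, outer-multiplied with
#' itself. It is strictly positive everywhere (no dead border rows), maximal
#' at the tile centre, and satisfies constant overlap-add at 50% overlap:
#' `h(i) + h(i + N/2) = 1`, so with a 128 px stride on 256 px tiles the
#' interior synthesis weights sum to exactly 1 before normalisation.
#'
#' @param tile_size tile side, px (>= 2).
#' @return `tile_size x tile_size` numeric mask.
#' @export
blend_weight_mask <- function(tile_size) {
  check_scalar(tile_size, "tile_size", 2, integerish = TRUE)
  h <- sin(pi * (seq_len(tile_size) - 0.5) / tile_size)^2
  outer(h, h)
}

#' Merge a focal stack into one deep-focus image
#'
#' The full tiled merging procedure: pick the burst window of consecutive
#' frames around the best-focused frame, run [fba_merge()] on every
#' overlapping tile of the window frames, and synthesise the merged tiles by
#' Hann-weighted overlap-add followed by pixelwise normalisation with the
#' accumulated blend weights (a partition of unity on the tile interior;
#' the clamped edge tiles are handled by the same normalisation).
#' Deterministic: identical inputs give bit-identical output.
#'
#' @param stack a [focal_stack()].
#' @param best_index 1-based index of the best-focused frame, or `"auto"`
#'   to select it as the frame of maximal Laplacian energy
#'   ([select_best_frame()]); the acquisition device's own criterion is
#'   proprietary, so maximal sharpness is used as the standard proxy.
#' @param params an [fba_params()] object.
#' @return object of class `merge_result`: list with `image` (merged
#'   `h x w x 3` array), `best_index`, `frame_window` (`c(first, last)`),
#'   `params` and `tile_grid`.
#' @export
focus_stack <- function(stack, best_index = "auto", params = fba_params()) {
  stop_if(!inherits(stack, "focal_stack"), "`stack` must be a focal_stack")
  stop_if(!inherits(params, "fba_params"), "`params` must be an fba_params object")
  n <- length(stack$frames)
  if (identical(best_index, "auto")) best_index <- select_best_frame(stack)
  check_scalar(best_index, "best_index", 1, integerish = TRUE)
  stop_if(best_index > n, "`best_index` is out of range")

  win <- select_frame_window(best_index, n, params$window_size,
                             params$foreground_bias)
  frames <- stack$frames[win[1]:win[2]]
  d <- stack_dim(stack)
  ts <- min(params$tile_size, d[1], d[2])  # small stacks: shrink tile to fit
  grid <- plan_tiles(d[1], d[2], ts, min(params$stride, ts))
  mask <- blend_weight_mask(ts)

  canvas <- array(0, c(d[1], d[2], 3L))
  wsum <- matrix(0, d[1], d[2])
  for (t in seq_len(nrow(grid$origins))) {
    r0 <- grid$origins[t, "row"]; c0 <- grid$origins[t, "col"]
    ri <- r0:(r0 + ts - 1L); ci <- c0:(c0 + ts - 1L)
    tiles <- lapply(frames, function(f) f[ri, ci, , drop = FALSE])
    merged <- fba_merge(tiles, params)
    for (ch in 1:3) {
      canvas[ri, ci, ch] <- canvas[ri, ci, ch] + merged[, , ch] * mask
    }
    wsum[ri, ci] <- wsum[ri, ci] + mask
  }
  for (ch in 1:3) canvas[, , ch] <- canvas[, , ch] / wsum
  structure(list(image = clip01(canvas), best_index = as.integer(best_index),
                 frame_window = win, params = params, tile_grid = grid),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<merge_result> %d x %d px; best frame %d, window %d..%d, %d tiles\n",
              d[1], d[2], x$best_index, x$frame_window[1], x$frame_window[2],
              nrow(x$tile_grid$origins)))
  invisible(x)
}
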