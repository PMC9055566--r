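#' Fourier Burst Accumulation parameters
#'
#' Bundles the tuning parameters of the tiled Fourier Burst Accumulation
#' merge. The tile geometry (256 px tiles shifted by 128 px) and the 7-frame
#' burst window reproduce the gonioscopic merging procedure; the spectral
#' exponent `p = 11` and magnitude smoothing `mag_sigma = 2` frequency bins
#' follow the original burst-accumulation method, which the merging
#' procedure builds on without restating them.
#'
#' @param p nonnegative spectral-weight exponent. `p = 0` gives the plain
#'   pixelwise mean of the burst; large `p` approaches per-frequency
#'   selection of the frame with the strongest (smoothed) spectrum.
#' @param mag_sigma Gaussian smoothing width for the spectrum magnitudes,
#'   in frequency bins; 0 disables smoothing.
#' @param window_size number of consecutive frames per burst.
#' @param tile_size side of the square local regions, px.
#' @param stride shift between neighbouring tiles, px.
#' @param sharpen if `TRUE`, apply a mild final unsharp mask
#'   (amount 0.5, sigma 1 px) to the merged image.
#' @param per_channel_weights if `TRUE`, compute spectral weights per colour
#'   channel instead of once from luminance (experimental; luminance-shared
#'   weights avoid colour fringing and are the default).
#' @param foreground_bias if `TRUE`, the burst window ends at the
#'   best-focused frame instead of being centred on it
#'   (see [select_frame_window()]).
#' @param grayscale_weights luma weights used wherever RGB frames are
#'   reduced to luminance.
#' @return an object of class `fba_params`.
#' @export
fba_params <- function(p = 11, mag_sigma = 2, window_size = 7,
                       tile_size = 256, stride = 128, sharpen = FALSE,
                       per_channel_weights = FALSE, foreground_bias = FALSE,
                       grayscale_weights = c(0.299, 0.587, 0.114)) {
  check_scalar(p, "p", 0)
  check_scalar(mag_sigma, "mag_sigma", 0)
  check_scalar(window_size, "window_size", 1, integerish = TRUE)
  check_scalar(tile_size, "tile_size", 1, integerish = TRUE)
  check_scalar(stride, "stride", 1, integerish = TRUE)
  stop_if(stride > tile_size, "`stride` must not exceed `tile_size`")
  structure(list(p = p, mag_sigma = mag_sigma,
                 window_size = as.integer(window_size),
                 tile_size = as.integer(tile_size),
                 stride = as.integer(stride),
                 sharpen = isTRUE(sharpen),
                 per_channel_weights = isTRUE(per_channel_weights),
                 foreground_bias = isTRUE(foreground_bias),
                 grayscale_weights = grayscale_weights),
            class = "fba_params")
}

#' @export
print.fba_params <- function(x, ...) {
  cat(sprintf(paste0("<fba_params> p=%g, mag_sigma=%g, window=%d, ",
                     "tile=%d/stride=%d, sharpen=%s\n"),
              x$p, x$mag_sigma, x$window_size, x$tile_size, x$stride,
              x$sharpen))
  invisible(x)
}

# Periodically wrapped, normalised 1-D Gaussian of length n: tap k holds the
# sum of the continuous Gaussian over all integer offsets congruent to k
# modulo n. Used because the discrete spectrum is periodic.
wrapped_gaussian_1d <- function(n, sigma) {
  k <- seq_len(n) - 1L
  v <- rep(0, n)
  for (m in -3:3) v <- v + exp(-((k + m * n)^2) / (2 * sigma^2))
  v / sum(v)
}

#' Smooth a Fourier magnitude plane
#'
#' Circular (wrap-around) Gaussian filtering of a spectrum-magnitude plane:
#' the discrete Fourier spectrum is periodic, so the filter wraps across the
#' plane edges. `mag_sigma = 0` returns the input unchanged.
#'
#' @param mag `h x w` nonnegative magnitude plane.
#' @param mag_sigma Gaussian width in frequency bins.
#' @param kernel_fft optional precomputed `fft(smoothing kernel)` of
#'   matching size, as returned by [smoothing_kernel_fft()]; avoids
#'   rebuilding the kernel when many planes of the same size are smoothed.
#' @return smoothed `h x w` plane.
#' @export
smooth_magnitude <- function(mag, mag_sigma, kernel_fft = NULL) {
  check_scalar(mag_sigma, "mag_sigma", 0)
  stop_if(!is.matrix(mag), "`mag` must be a matrix")
  if (mag_sigma == 0) return(mag)
  if (is.null(kernel_fft)) {
    kernel_fft <- smoothing_kernel_fft(nrow(mag), ncol(mag), mag_sigma)
  }
  out <- Re(fft(fft(mag) * kernel_fft, inverse = TRUE)) / length(mag)
  pmax(out, 0)  # clamp tiny negative FFT round-off
}

#' Precompute the transform of the circular smoothing kernel
#'
#' @param h,w plane extent in frequency bins.
#' @param mag_sigma Gaussian width in frequency bins.
#' @return complex `h x w` matrix, `fft` of the wrapped Gaussian kernel.
#' @export
smoothing_kernel_fft <- function(h, w, mag_sigma) {
  fft(outer(wrapped_gaussian_1d(h, mag_sigma),
            wrapped_gaussian_1d(w, mag_sigma)))
}

#' Per-frequency spectral weights
#'
#' Weight of frame i at frequency bin zeta is
#' `M_i(zeta)^p / sum_j M_j(zeta)^p`. Where every frame has zero (smoothed)
#' magnitude the weights fall back to the uniform `1/n`. Magnitudes are
#' normalised by the per-bin maximum before exponentiation so that large
#' exponents do not overflow.
#'
#' @param smoothed_mags `h x w x n` array of nonnegative magnitudes, one
#'   slice per frame.
#' @param p nonnegative exponent.
#' @return `h x w x n` array of weights summing to 1 across the third
#'   dimension at every bin.
#' @export
fourier_weights <- function(smoothed_mags, p) {
  check_scalar(p, "p", 0)
  stop_if(!is.array(smoothed_mags) || length(dim(smoothed_mags)) != 3L,
          "`smoothed_mags` must be an h x w x n array")
  d <- dim(smoothed_mags)
  n <- d[3]
  mx <- smoothed_mags[, , 1]
  if (n > 1L) for (i in 2:n) mx <- pmax(mx, smoothed_mags[, , i])
  safe_mx <- ifelse(mx > 0, mx, 1)
  w <- (smoothed_mags / array(safe_mx, d))^p
  tot <- array(0, d[1:2])
  for (i in seq_len(n)) tot <- tot + w[, , i]
  zero <- tot == 0 | mx == 0
  for (i in seq_len(n)) {
    wi <- w[, , i] / tot
    wi[zero] <- 1 / n
    w[, , i] <- wi
  }
  w
}

unsharp_mask <- function(img, amount = 0.5, sigma = 1) {
  map_channels(img, function(m) m + amount * (m - gaussian_blur_matrix(m, sigma)))
}

#' Merge a burst of co-registered frames by Fourier Burst Accumulation
#'
#' Each frame's luminance is Fourier transformed; the magnitude planes are
#' smoothed and converted to per-frequency weights ([fourier_weights()]);
#' the frames' spectra are averaged with those weights (the same
#' luminance-derived weights for all colour channels, unless
#' `per_channel_weights`); the inverse transform's real part, clipped to
#' `[0, 255]`, is the merged image. Frequencies where a frame is sharp carry
#' large magnitude, so the merge keeps each frequency mostly from the frames
#' that rendered it sharply -- no blur kernel is ever estimated.
#'
#' @param frames list of frames, all grayscale matrices or all `h x w x 3`
#'   arrays of identical size, 0-255 scale.
#' @param params an [fba_params()] object.
#' @return merged image of the same kind and size as the inputs.
#' @export
fba_merge <- function(frames, params = fba_params()) {
  stop_if(!is.list(frames) || length(frames) == 0L, "`frames` must be a nonempty list")
  stop_if(!inherits(params, "fba_params"), "`params` must be an fba_params object")
  dims <- lapply(frames, function(f) dim(f)[1:2])
  stop_if(!all(vapply(dims, identical, logical(1), dims[[1]])),
          "all frames must share identical dimensions")
  n <- length(frames)
  h <- dims[[1]][1]; w <- dims[[1]][2]
  rgb <- !is.matrix(frames[[1]])

  lum_fft <- lapply(frames, function(f) {
    fft(if (rgb) to_grayscale(f, params$grayscale_weights) else f)
  })
  kfft <- if (params$mag_sigma > 0) smoothing_kernel_fft(h, w, params$mag_sigma)
  weight_for <- function(ffts) {
    mags <- array(0, c(h, w, n))
    for (i in seq_len(n)) {
      mags[, , i] <- smooth_magnitude(Mod(ffts[[i]]), params$mag_sigma, kfft)
    }
    fourier_weights(mags, params$p)
  }
  wts <- weight_for(lum_fft)

  merge_plane <- function(plane_ffts, wts) {
    acc <- matrix(0 + 0i, h, w)
    for (i in seq_len(n)) acc <- acc + wts[, , i] * plane_ffts[[i]]
    Re(fft(acc, inverse = TRUE)) / (h * w)
  }

  out <- if (!rgb) {
    merge_plane(lum_fft, wts)
  } else {
    res <- array(0, c(h, w, 3L))
    for (ch in 1:3) {
      ch_ffts <- lapply(frames, function(f) fft(f[, , ch]))
      ch_wts <- if (params$per_channel_weights) weight_for(ch_ffts) else wts
      res[, , ch] <- merge_plane(ch_ffts, ch_wts)
    }
    res
  }
  if (params$sharpen) out <- unsharp_mask(out)
  clip01(out)
}
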