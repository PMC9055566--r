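# Minimal baseline TIFF codec (little-endian, uncompressed, single strip).
# The environment offers PNG and JPEG codecs but no TIFF one, so the small
# subset needed here -- 8-bit gray/RGB images and 32-bit float planes such
# as depth-map sidecars -- is implemented directly against the TIFF 6.0
# baseline. Only files written by this codec (or equally plain baseline
# TIFFs) are readable; compressed or big-endian files are rejected with a
# clear error.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

tiff_entry <- function(tag, type, count, value_raw) {
  # value_raw: raw vector, <= 4 bytes (inline) -- pad to 4
  c(u16(tag), u16(type), u32(count), value_raw, raw(4 - length(value_raw)))
}

write_tiff_raw <- function(image, path, sample_format = c("uint8", "float32")) {
  sample_format <- match.arg(sample_format)
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  h <- dim(image)[1]; w <- dim(image)[2]; spp <- dim(image)[3]
  stop_if(!spp %in% c(1L, 3L), "TIFF writer supports 1 or 3 samples per pixel")

  bps <- if (sample_format == "uint8") 8L else 32L
  fmt <- if (sample_format == "uint8") 1L else 3L
  # interleave samples row-major: (sample, col, row) fastest-first
  vec <- as.vector(aperm(image, c(3, 2, 1)))
  pix <- if (sample_format == "uint8") {
    as.raw(as.integer(round(clip01(vec))))
  } else {
    writeBin(as.numeric(vec), raw(), size = 4, endian = "little")
  }

  n_entries <- 10L
  ifd_off <- 8L
  after_ifd <- ifd_off + 2L + 12L * n_entries + 4L
  # external arrays (BitsPerSample / SampleFormat) only needed when spp == 3
  bps_off <- after_ifd
  fmt_off <- bps_off + if (spp == 3L) 6L else 0L
  data_off <- fmt_off + if (spp == 3L) 6L else 0L

  bps_val <- if (spp == 1L) u16(bps) else u32(bps_off)
  fmt_val <- if (spp == 1L) u16(fmt) else u32(fmt_off)
  entries <- c(
    tiff_entry(256L, 3L, 1L, u16(w)),                       # ImageWidth
    tiff_entry(257L, 3L, 1L, u16(h)),                       # ImageLength
    tiff_entry(258L, 3L, spp, bps_val),                     # BitsPerSample
    tiff_entry(259L, 3L, 1L, u16(1L)),                      # Compression: none
    tiff_entry(262L, 3L, 1L, u16(if (spp == 3L) 2L else 1L)), # Photometric
    tiff_entry(273L, 4L, 1L, u32(data_off)),                # StripOffsets
    tiff_entry(277L, 3L, 1L, u16(spp)),                     # SamplesPerPixel
    tiff_entry(278L, 3L, 1L, u16(h)),                       # RowsPerStrip
    tiff_entry(279L, 4L, 1L, u32(length(pix))),             # StripByteCounts
    tiff_entry(339L, 3L, spp, fmt_val)                      # SampleFormat
  )
  out <- c(charToRaw("II"), u16(42L), u32(ifd_off),
           u16(n_entries), entries, u32(0L))
  if (spp == 3L) out <- c(out, u16(rep(bps, 3L)), u16(rep(fmt, 3L)))
  out <- c(out, pix)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

read_u <- function(buf, off, size, n = 1L) {
  readBin(buf[(off + 1L):(off + size * n)], "integer", n = n, size = size,
          endian = "little", signed = size == 4)
}

tiff_field <- function(buf, entry_off) {
  tag <- read_u(buf, entry_off, 2L)
  type <- read_u(buf, entry_off + 2L, 2L)
  count <- read_u(buf, entry_off + 4L, 4L)
  size <- c(1L, 1L, 2L, 4L, 8L)[type]  # BYTE ASCII SHORT LONG RATIONAL
  nbytes <- size * count
  val_off <- if (nbytes <= 4L) entry_off + 8L else read_u(buf, entry_off + 8L, 4L)
  values <- if (type %in% c(3L, 4L)) read_u(buf, val_off, size, count) else NA
  list(tag = tag, values = values)
}

# Returns, like png::readPNG, an array in [0,1] for integer samples; float
# samples are returned as stored.
read_tiff_raw <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  stop_if(length(buf) < 8L || rawToChar(buf[1:2]) != "II" || read_u(buf, 2L, 2L) != 42L,
          "not a little-endian TIFF file: ", path)
  ifd <- read_u(buf, 4L, 4L)
  n <- read_u(buf, ifd, 2L)
  fields <- lapply(seq_len(n) - 1L, function(i) tiff_field(buf, ifd + 2L + 12L * i))
  tagval <- function(tag, default = NULL) {
    for (f in fields) if (f$tag == tag) return(f$values)
    default
  }
  w <- tagval(256L); h <- tagval(257L)
  stop_if(is.null(w) || is.null(h), "TIFF missing dimensions: ", path)
  stop_if(tagval(259L, 1L)[1] != 1L, "compressed TIFF not supported: ", path)
  spp <- tagval(277L, 1L)[1]
  bps <- tagval(258L, 8L)[1]
  fmt <- tagval(339L, 1L)[1]
  offs <- tagval(273L); cnts <- tagval(279L)
  stop_if(is.null(offs) || is.null(cnts), "TIFF missing strip layout: ", path)
  pix_raw <- do.call(c, lapply(seq_along(offs), function(i) {
    buf[(offs[i] + 1L):(offs[i] + cnts[i])]
  }))
  vec <- if (fmt == 3L) {
    stop_if(bps != 32L, "only 32-bit float TIFF supported: ", path)
    readBin(pix_raw, "numeric", n = w * h * spp, size = 4, endian = "little")
  } else if (bps == 8L) {
    as.integer(pix_raw) / 255
  } else if (bps == 16L) {
    readBin(pix_raw, "integer", n = w * h * spp, size = 2,
            endian = "little", signed = FALSE) / 65535
  } else {
    stop("unsupported TIFF bit depth ", bps, " (only 8/16-bit integer or 32-bit float): ",
         path, call. = FALSE)
  }
  arr <- aperm(array(vec, c(spp, w, h)), c(3, 2, 1))
  if (spp == 1L) arr[, , 1L] else arr
}

#' Write / read a real-valued map as 32-bit float TIFF
#'
#' Used for depth-map sidecars, which need fractional values in `[0, 1]`
#' that an 8-bit raster could not carry.
#'
#' @param map numeric matrix.
#' @param path output `.tif`/`.tiff` path.
#' @export
write_float_map <- function(map, path) {
  stop_if(!is.matrix(map), "`map` must be a matrix")
  write_tiff_raw(map, path, sample_format = "float32")
}

#' @rdname write_float_map
#' @export
read_float_map <- function(path) {
  out <- read_tiff_raw(path)
  stop_if(!is.matrix(out), "expected a single-plane float TIFF: ", path)
  out
}
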