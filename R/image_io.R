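#' @title Image and focal-stack input/output
#'
#' @description Images are held in memory on the 0-255 intensity scale as
#' plain numeric structures: an RGB image is a `height x width x 3` array, a
#' grayscale image a `height x width` matrix. A focal stack is an ordered
#' list of equally sized RGB frames, index 1 being the frame nearest the
#' gonio-prism (foreground). All arithmetic throughout the package stays on
#' the 0-255 scale so that reported Laplacian energies are directly
#' comparable across images and tools.
#'
#' @name image_io
NULL

#' Construct a focal stack
#'
#' @param frames list of RGB images (`h x w x 3` numeric arrays, 0-255
#'   scale), ordered from foreground (nearest the gonio-prism) to
#'   background.
#' @param sector_id optional integer 1..16 identifying the mirrored sector
#'   the stack was acquired from.
#' @return An object of class `focal_stack`: a list with elements `frames`,
#'   `focal_indices` (1..n, foreground first), and `sector_id`.
#' @export
focal_stack <- function(frames, sector_id = NULL) {
  stop_if(!is.list(frames) || length(frames) == 0L,
          "a focal stack needs at least one frame")
  dims <- lapply(frames, function(f) dim(f)[1:2])
  ref <- dims[[1]]
  same <- vapply(dims, function(d) identical(d, ref), logical(1))
  stop_if(!all(same),
          "all frames must share identical dimensions; offending frames: ",
          paste(which(!same), collapse = ", "))
  if (!is.null(sector_id)) check_scalar(sector_id, "sector_id", 1, integerish = TRUE)
  structure(
    list(frames = frames,
         focal_indices = seq_along(frames),
         sector_id = if (is.null(sector_id)) NULL else as.integer(sector_id)),
    class = "focal_stack")
}

#' @export
length.focal_stack <- function(x) length(x$frames)

#' @export
print.focal_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<focal_stack> %d frame(s), %d x %d px%s\n",
              length(x$frames), d[1], d[2],
              if (is.null(x$sector_id)) "" else sprintf(", sector %d", x$sector_id)))
  invisible(x)
}

stack_dim <- function(stack) dim(stack$frames[[1]])[1:2]

# Normalise any decoded raster (matrix, h x w x {1,2,3,4}) to h x w x 3 on
# the 0-255 scale. Alpha channels are dropped; gray planes are replicated.
as_rgb_array <- function(px) {
  if (is.matrix(px)) px <- array(px, c(dim(px), 1L))
  nch <- dim(px)[3]
  if (nch == 2L) px <- px[, , 1L, drop = FALSE]          # gray + alpha
  if (nch == 4L) px <- px[, , 1:3, drop = FALSE]          # rgb + alpha
  if (dim(px)[3] == 1L) px <- array(px, c(dim(px)[1:2], 3L))
  px * 255
}

#' Load a raster image
#'
#' Reads a PNG, TIFF or JPEG file into an RGB image on the 0-255 scale.
#' 8-bit and 16-bit files are accepted; 16-bit samples are rescaled onto
#' 0-255. Grayscale files are replicated across the three channels.
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return `h x w x 3` numeric array with values in `[0, 255]`.
#' @export
load_image <- function(path) {
  stop_if(!is.character(path) || length(path) != 1L, "`path` must be a single file path")
  stop_if(!file.exists(path), "cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      tif  = ,
      tiff = read_tiff_raw(path),
      stop("unsupported image format '", ext, "' for: ", path)),
    error = function(e) stop("failed to decode image ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  as_rgb_array(px)
}

#' Save an image losslessly
#'
#' Writes an RGB image (`h x w x 3`) or grayscale image (`h x w` matrix) as
#' 8-bit PNG or uncompressed TIFF. Values are rounded to the nearest integer
#' and clipped to `[0, 255]` before encoding, so a save/load round trip is
#' exact for integer-valued input and within 0.5 otherwise.
#'
#' @param image numeric matrix or `h x w x 3` array on the 0-255 scale.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @export
save_image <- function(image, path) {
  stop_if(!is.numeric(image) || !(is.matrix(image) || (is.array(image) && length(dim(image)) == 3L)),
          "`image` must be a numeric matrix or h x w x 3 array")
  dir <- dirname(path)
  stop_if(!dir.exists(dir), "cannot write image: no such directory: ", dir)
  q <- round(clip01(image))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(q / 255, path),
    tif  = ,
    tiff = write_tiff_raw(q, path, sample_format = "uint8"),
    stop("unsupported output format '", ext, "' (use png or tiff): ", path))
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' Uses Rec. 601 luma weights by default (0.299 R + 0.587 G + 0.114 B), the
#' common still-image convention; the source images do not prescribe a
#' conversion, so the weights are exposed as an argument.
#'
#' @param image `h x w x 3` numeric array on the 0-255 scale.
#' @param weights length-3 nonnegative weights summing to 1.
#' @return `h x w` numeric matrix in `[0, 255]`.
#' @export
to_grayscale <- function(image, weights = c(0.299, 0.587, 0.114)) {
  if (is.matrix(image)) return(image)
  stop_if(length(dim(image)) != 3L || dim(image)[3] != 3L,
          "`image` must be an h x w x 3 array")
  stop_if(length(weights) != 3L || any(weights < 0),
          "`weights` must be 3 nonnegative numbers")
  weights[1] * image[, , 1] + weights[2] * image[, , 2] + weights[3] * image[, , 3]
}

#' Load a focal stack from a directory
#'
#' Matching files are sorted by name (C-locale lexicographic order), and the
#' sorted order defines the focal order: the first file is the foreground
#' plane. No metadata is consulted.
#'
#' @param directory directory containing one image file per focal plane.
#' @param pattern filename glob, default `"*.png"`.
#' @param sector_id optional sector label passed to [focal_stack()].
#' @return a [focal_stack()] object.
#' @export
load_stack <- function(directory, pattern = "*.png", sector_id = NULL) {
  stop_if(!dir.exists(directory), "no such directory: ", directory)
  files <- Sys.glob(file.path(directory, pattern))
  stop_if(length(files) == 0L,
          "no files matching '", pattern, "' in ", directory)
  files <- files[order(basename(files), method = "radix")]
  frames <- lapply(files, load_image)
  dims <- t(vapply(frames, function(f) dim(f)[1:2], integer(2)))
  bad <- !(dims[, 1] == dims[1, 1] & dims[, 2] == dims[1, 2])
  stop_if(any(bad), "frames have mixed dimensions: ",
          paste(basename(files)[bad], collapse = ", "))
  focal_stack(frames, sector_id = sector_id)
}
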