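#' Single-channel 8-bit image
#'
#' Light container for one fluorescence channel: an integer matrix of
#' intensities in [0, 255] plus the channel name and pixel size.
#'
#' @param intensities integer matrix, values in [0, 255]; rows are image rows
#'   (0-based, row-major pixel coordinates are used in all exported tables).
#' @param channel one of "DAPI", "S830", "LAMININ".
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @return An object of class `channel_image` (a matrix with attributes).
#' @export
channel_image <- function(intensities, channel = c("DAPI", "S830", "LAMININ"),
                          pixel_size_um = 0.31) {
  channel <- match.arg(channel)
  if (!is.matrix(intensities))
    stop("`intensities` must be a matrix")
  m <- intensities
  storage.mode(m) <- "integer"
  if (anyNA(m) || min(m) < 0L || max(m) > 255L)
    stop("intensities must be integers in [0, 255]")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar")
  structure(m, channel = channel, pixel_size_um = pixel_size_um,
            class = c("channel_image", "matrix", "array"))
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, %.3g um/px, range [%d, %d]\n",
              attr(x, "channel"), nrow(x), ncol(x),
              attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

# strip attributes; plain integer matrix
as_intensity_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "channel") <- NULL
  attr(m, "pixel_size_um") <- NULL
  storage.mode(m) <- "integer"
  m
}

# plain matrices carry no scale metadata: measurements stay in pixel units
pixel_size_of <- function(img, default = 1) {
  ps <- attr(img, "pixel_size_um")
  if (is.null(ps)) default else ps
}

#' Write a channel image as a single-page 8-bit grayscale TIFF
#'
#' @param img a [channel_image()] or integer matrix in [0, 255].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(img, path) {
  m <- as_intensity_matrix(img)
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a single-page grayscale TIFF as a channel image
#'
#' @param path TIFF file path.
#' @inheritParams channel_image
#' @return A [channel_image()].
#' @export
read_channel_tiff <- function(path, channel = c("DAPI", "S830", "LAMININ"),
                              pixel_size_um = 0.31) {
  if (!file.exists(path)) stop("image file not found: ", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]  # tolerate grey written as RGB
  channel_image(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
                channel = match.arg(channel), pixel_size_um = pixel_size_um)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL draws from the current stream (for outer Monte-Carlo loops).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a scalar in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}
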