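#' Read a grayscale image
#'
#' Reads a PNG or TIFF file and returns a numeric intensity matrix. Color
#' inputs are converted to luminance (Rec. 601 weights 0.299, 0.587, 0.114);
#' an alpha channel, if present, is dropped.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param scale `"unit"` returns intensities in `[0, 1]` as stored;
#'   `"integer"` rescales to integers in `[0, 2^bit_depth - 1]`.
#' @param bit_depth bit depth used for `scale = "integer"`.
#' @return A numeric matrix (rows = image rows).
#' @export
read_image <- function(path, scale = c("unit", "integer"), bit_depth = 8) {
  scale <- match.arg(scale)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  m <- to_gray(arr)
  if (scale == "integer") m <- round(m * (2^bit_depth - 1))
  m
}

to_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc >= 3) {
      return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
    }
    return(arr[, , 1])
  }
  stop("unrecognised image array layout")
}

#' Write a grayscale image
#'
#' @param image numeric matrix; either unit-interval intensities or integers
#'   in `[0, 2^bit_depth - 1]` (detected from the range and `max(image) > 1`).
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @param bit_depth bit depth for integer-valued input.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 8) {
  stopifnot(is.matrix(image))
  m <- image
  if (max(m) > 1 + 1e-9) m <- m / (2^bit_depth - 1)
  m <- pmin(pmax(m, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

# Padded index vector implementing the border policy for a 4-tap
# neighbourhood anchored at rows/cols 1..n (needs indices 0..n+2).
border_index <- function(n, border = c("replicate", "reflect")) {
  border <- match.arg(border)
  idx <- 0:(n + 2)
  if (border == "replicate") {
    pmin(pmax(idx, 1L), n)
  } else {
    # mirror about the edge pixels: 0 -> 2, n+1 -> n-1, n+2 -> n-2
    out <- idx
    out[idx < 1] <- 2L - idx[idx < 1]
    out[idx > n] <- 2L * n - idx[idx > n]
    pmin(pmax(out, 1L), n)
  }
}

# round half away from zero (round() in R rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
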