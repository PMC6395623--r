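#' Grayscale image container
#'
#' A `gray_image` is a 2D grid of non-negative, finite intensities in
#' `[0, 1]`-ish range (any non-negative scale is accepted: the directionality
#' statistics are intensity-scale invariant). Rows are image y (downward),
#' columns image x.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param source_id Free-text label carried through to results.
#' @return An object of class `gray_image` with fields `pixels`, `height_px`,
#'   `width_px`, `source_id`.
#' @export
gray_image <- function(pixels, source_id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_fibralign("pixels must be a numeric matrix", "fibralign_input_error")
  if (any(!is.finite(pixels)))
    stop_fibralign("image contains non-finite intensities",
                   "fibralign_input_error")
  if (any(pixels < 0))
    stop_fibralign("image contains negative intensities",
                   "fibralign_input_error")
  structure(
    list(pixels = pixels, height_px = nrow(pixels), width_px = ncol(pixels),
         source_id = as.character(source_id)),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %s: %d x %d px, intensity range [%.4g, %.4g]\n",
              x$source_id, x$height_px, x$width_px,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Load a micrograph and crop it to the analysis window
#'
#' Reads an 8/16-bit grayscale (or RGB, converted by luminance) TIFF or PNG,
#' maps intensities linearly to `[0, 1]`, and returns the central
#' `crop_px` x `crop_px` window. A common fixed crop keeps spectra of all
#' images in a series on the same frequency grid; the default of 825 px is
#' odd, so the centered spectrum has a true central DC pixel.
#'
#' @param path Path to a TIFF or PNG file.
#' @param crop_px Side of the centered square crop, in pixels (default 825).
#' @return A [gray_image] of size `crop_px` x `crop_px`.
#' @export
load_and_prepare <- function(path, crop_px = 825) {
  if (!is.numeric(crop_px) || length(crop_px) != 1 || crop_px < 1)
    stop_fibralign("crop_px must be a positive integer",
                   "fibralign_parameter_error")
  if (!file.exists(path))
    stop_fibralign(sprintf("file not found: %s", path),
                   "fibralign_input_error")
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           tif = , tiff = tiff::readTIFF(path),
           png = png::readPNG(path),
           stop_fibralign(
             sprintf("unsupported image format '%s' (need TIFF or PNG)", ext),
             "fibralign_input_error")),
    error = function(e) {
      if (inherits(e, "fibralign_error")) stop(e)
      stop_fibralign(sprintf("could not decode %s: %s", path,
                             conditionMessage(e)),
                     "fibralign_input_error")
    })
  px <- as_luminance(arr)
  h <- nrow(px); w <- ncol(px)
  if (h < crop_px || w < crop_px)
    stop_fibralign(
      sprintf("image %s is %d x %d px; both dimensions must be >= %d",
              path, h, w, crop_px),
      "fibralign_size_error")
  px <- central_crop(px, crop_px)
  gray_image(px, source_id = basename(path))
}

# Collapse a decoded array to a single luminance channel in [0,1].
# readTIFF/readPNG already rescale bit depth linearly to [0,1].
as_luminance <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc == 1) return(arr[, , 1])
    if (nc >= 3)  # Rec.601 luma; alpha, if present, is ignored
      return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
    if (nc == 2) return(arr[, , 1])  # gray + alpha
  }
  stop_fibralign("unsupported image layout", "fibralign_input_error")
}

central_crop <- function(px, crop_px) {
  h <- nrow(px); w <- ncol(px)
  r0 <- floor((h - crop_px) / 2)
  c0 <- floor((w - crop_px) / 2)
  px[(r0 + 1):(r0 + crop_px), (c0 + 1):(c0 + crop_px), drop = FALSE]
}
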