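#' Centered FFT modulus of a grayscale image
#'
#' Computes the modulus of the 2D discrete Fourier transform of the image and
#' recenters it so the zero-frequency (DC) term sits at the central pixel
#' (row `floor(H/2)+1`, column `floor(W/2)+1`). The modulus is treated
#' downstream as an unnormalized probability mass over centered frequency
#' coordinates; its asymmetry encodes the orientation of structures in the
#' image.
#'
#' @param img A [gray_image], or a plain numeric matrix.
#' @param window `"none"` (default) or `"hann"`. A 2D Hann taper suppresses
#'   the axis-aligned cross artifact produced by the rectangular crop; the
#'   default is no window.
#' @return A `spectrum_distribution` with fields `modulus` (centered, same
#'   shape as the image), `cutoff` (initialized to 0), `dc_excluded` (FALSE),
#'   and `dim`.
#' @export
compute_spectrum <- function(img, window = c("none", "hann")) {
  window <- match.arg(window)
  px <- if (inherits(img, "gray_image")) img$pixels else img
  if (!is.matrix(px) || !is.numeric(px))
    stop_fibralign("expected a gray_image or numeric matrix",
                   "fibralign_input_error")
  if (any(!is.finite(px)))
    stop_fibralign("image contains non-finite pixels", "fibralign_input_error")
  if (window == "hann") {
    hr <- hann_vec(nrow(px)); hc <- hann_vec(ncol(px))
    px <- px * outer(hr, hc)
  }
  m <- Mod(stats::fft(px))
  m <- m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m))]
  structure(
    list(modulus = m, cutoff = 0, dc_excluded = FALSE, dim = dim(m),
         source_id = if (inherits(img, "gray_image")) img$source_id else "matrix"),
    class = "spectrum_distribution")
}

hann_vec <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' @export
print.spectrum_distribution <- function(x, ...) {
  cat(sprintf(
    "<spectrum_distribution> %d x %d, cutoff = %.4g, DC %s, total mass %.4g\n",
    x$dim[1], x$dim[2], x$cutoff,
    if (x$dc_excluded) "excluded" else "included", sum(x$modulus)))
  invisible(x)
}

#' Noise floor from the corners of the centered spectrum
#'
#' The four `corner_px` x `corner_px` blocks at the corners of the centered
#' modulus matrix hold the highest spatial frequencies, where fibrous images
#' carry essentially no structural signal; the largest modulus value found
#' there estimates the noise ceiling of the whole spectrum and is used as the
#' threshold below which spectral values are zeroed.
#'
#' @param spec A `spectrum_distribution` from [compute_spectrum()].
#' @param corner_px Side of each corner block (default 64).
#' @return A single non-negative number: the maximum modulus over the four
#'   corner blocks.
#' @export
estimate_noise_cutoff <- function(spec, corner_px = 64) {
  stopifnot(inherits(spec, "spectrum_distribution"))
  h <- spec$dim[1]; w <- spec$dim[2]
  if (!is.numeric(corner_px) || length(corner_px) != 1 || corner_px < 1)
    stop_fibralign("corner_px must be a positive integer",
                   "fibralign_parameter_error")
  if (corner_px > floor(min(h, w) / 2) - 1)
    stop_fibralign(
      sprintf("corner_px = %d too large for a %d x %d spectrum: blocks would reach the center",
              corner_px, h, w),
      "fibralign_parameter_error")
  m <- spec$modulus
  top <- m[seq_len(corner_px), c(seq_len(corner_px), (w - corner_px + 1):w)]
  bot <- m[(h - corner_px + 1):h, c(seq_len(corner_px), (w - corner_px + 1):w)]
  max(top, bot)
}

#' Zero spectral values below a cutoff
#'
#' Applies the noise threshold: every modulus value strictly below `cutoff`
#' is set to 0. By default the DC pixel is zeroed too, since it encodes mean
#' image brightness, not orientation, and its angle is undefined.
#'
#' @param spec A `spectrum_distribution`.
#' @param cutoff Non-negative threshold, typically from
#'   [estimate_noise_cutoff()].
#' @param exclude_dc Zero the central (DC) pixel as well (default TRUE).
#' @return The thresholded `spectrum_distribution` with `cutoff` and
#'   `dc_excluded` recorded.
#' @export
apply_cutoff <- function(spec, cutoff, exclude_dc = TRUE) {
  stopifnot(inherits(spec, "spectrum_distribution"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0)
    stop_fibralign("cutoff must be a single non-negative number",
                   "fibralign_parameter_error")
  m <- spec$modulus
  total_before <- sum(m)
  m[m < cutoff] <- 0
  if (exclude_dc) m[dc_index(nrow(m)), dc_index(ncol(m))] <- 0
  # relative guard: mass at the level of FFT roundoff counts as none
  if (sum(m) <= 1e-9 * total_before)
    stop_fibralign(
      "cutoff removed all spectral mass (blank or noise-only image)",
      "fibralign_degenerate_spectrum_error")
  spec$modulus <- m
  spec$cutoff <- cutoff
  spec$dc_excluded <- isTRUE(exclude_dc) || spec$dc_excluded
  spec
}

#' Log-scaled display normalization of a spectrum
#'
#' Maps the modulus through `log(1 + x)` and rescales the result linearly to
#' `[0, 1]` for visualization. Never used by the statistics.
#'
#' @param spec A `spectrum_distribution`.
#' @return A numeric matrix in `[0, 1]` of the same shape. A constant
#'   spectrum (min = max) maps to all zeros.
#' @export
log_display_normalize <- function(spec) {
  stopifnot(inherits(spec, "spectrum_distribution"))
  g <- log1p(spec$modulus)
  rng <- range(g)
  if (rng[2] <= rng[1]) return(array(0, dim = dim(g)))
  (g - rng[1]) / (rng[2] - rng[1])
}
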