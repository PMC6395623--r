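#' Analysis configuration
#'
#' Bundles the tunable parameters of the directionality pipeline.
#'
#' @param crop_px Side of the centered square crop (default 825; odd values
#'   are recommended so the spectrum has a true central DC pixel — a warning
#'   is issued otherwise).
#' @param corner_px Side of the corner noise-estimation blocks (default 64);
#'   must satisfy `corner_px <= (crop_px - 1)/2 - 1`.
#' @param n_sectors Number of angular sectors over 180 degrees (default 180).
#' @param window Spectral taper, `"none"` (default, no apodization) or
#'   `"hann"`.
#' @param exclude_dc Zero the DC pixel before moments and sector sums
#'   (default TRUE).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(crop_px = 825, corner_px = 64, n_sectors = 180,
                            window = c("none", "hann"), exclude_dc = TRUE) {
  window <- match.arg(window)
  if (crop_px %% 2 == 0)
    warning("crop_px is even; DC sits at floor(N/2)+1 with a one-pixel ",
            "Nyquist asymmetry. An odd crop_px is recommended.")
  if (corner_px > (crop_px - 1) / 2 - 1)
    stop_fibralign("corner_px too large for crop_px: corner blocks would reach the center",
                   "fibralign_parameter_error")
  structure(list(crop_px = crop_px, corner_px = corner_px,
                 n_sectors = n_sectors, window = window,
                 exclude_dc = exclude_dc),
            class = "analysis_config")
}

#' Full image-to-alignment-statistics pipeline
#'
#' Runs the complete directionality analysis on one image: central crop,
#' 2D FFT modulus centered on DC, noise cutoff estimated from the maxima of
#' the corner subarrays, thresholding, second-order central moments and
#' equivalent covariance ellipse (eccentricity \eqn{\varepsilon}, prevailing
#' direction \eqn{\mu}), and the normalized angular sector distribution
#' fitted with a normal (angular standard deviation \eqn{\sigma}).
#'
#' @param image A file path (TIFF/PNG) or a [gray_image].
#' @param config An [analysis_config()] (defaults used if omitted).
#' @return An `alignment_result` with `eccentricity_eps`, `mu_deg` (degrees,
#'   `[0, 180)`), `sigma_deg` (degrees, `[0, 90]`), the `moment_summary`,
#'   the frequency-domain ellipse angle, the fitted angular distribution,
#'   the cutoff used, and diagnostic `flags`.
#' @export
analyze_image <- function(image, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, fibralign_error = function(e) {
      e$message <- sprintf("[%s] %s", name, conditionMessage(e))
      stop(e)
    })
  }
  img <- if (inherits(image, "gray_image")) {
    if (img_needs_crop(image, config$crop_px))
      stage("load_and_prepare",
            gray_image(central_crop(image$pixels, config$crop_px),
                       source_id = image$source_id))
    else image
  } else {
    stage("load_and_prepare", load_and_prepare(image, config$crop_px))
  }
  spec   <- stage("compute_spectrum", compute_spectrum(img, config$window))
  cutoff <- stage("estimate_noise_cutoff",
                  estimate_noise_cutoff(spec, config$corner_px))
  spec   <- stage("apply_cutoff",
                  apply_cutoff(spec, cutoff, config$exclude_dc))
  mom    <- stage("second_order_moments", second_order_moments(spec))
  ell    <- stage("equivalent_ellipse", equivalent_ellipse(mom))
  mu     <- stage("prevailing_direction",
                  prevailing_direction(ell$ellipse_angle_freq_deg))
  ang    <- stage("angular_sector_distribution",
                  angular_sector_distribution(spec, config$n_sectors))
  ang    <- stage("fit_angular_normal", fit_angular_normal(ang))
  flags <- character()
  if (ell$eccentricity_eps < 1e-3) flags <- c(flags, "orientation_unreliable")
  # almost nothing above the noise cutoff: blank or noise-only image
  if (mean(spec$modulus > 0) < 1e-3) flags <- c(flags, "low_spectral_mass")
  structure(
    list(source_id = img$source_id,
         eccentricity_eps = ell$eccentricity_eps,
         mu_deg = mu,
         sigma_deg = ang$fit_sigma_deg,
         ellipse_angle_freq_deg = ell$ellipse_angle_freq_deg,
         moments = mom,
         angular = ang,
         cutoff = cutoff,
         config = config,
         flags = flags),
    class = "alignment_result")
}

img_needs_crop <- function(img, crop_px) {
  img$height_px != crop_px || img$width_px != crop_px
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s\n", x$source_id))
  cat(sprintf("  eccentricity eps = %.3f\n", x$eccentricity_eps))
  cat(sprintf("  prevailing direction mu = %.1f deg\n", x$mu_deg))
  cat(sprintf("  angular SD sigma = %.1f deg\n", x$sigma_deg))
  cat(sprintf("  noise cutoff = %.4g\n", x$cutoff))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' One-row data frame view of an alignment result
#'
#' @param x An `alignment_result`.
#' @param ... Unused.
#' @return A one-row data frame with the headline statistics and parameters.
#' @export
as.data.frame.alignment_result <- function(x, ...) {
  data.frame(source_id = x$source_id,
             crop_px = x$config$crop_px,
             corner_px = x$config$corner_px,
             cutoff = x$cutoff,
             eccentricity = x$eccentricity_eps,
             mu_deg = x$mu_deg,
             sigma_deg = x$sigma_deg,
             n_sectors = x$config$n_sectors,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
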