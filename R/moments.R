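#' Second-order central moments of a spectral mass distribution
#'
#' Treats the (thresholded) centered FFT modulus as a probability mass
#' function over integer frequency coordinates \eqn{(u, v)} (u along columns,
#' v along rows, origin at the DC pixel) and computes the centroid and the
#' three independent second-order central moments
#' \eqn{\mu_{20} = \sum w (u-\bar u)^2}, \eqn{\mu_{02} = \sum w (v-\bar v)^2},
#' \eqn{\mu_{11} = \sum w (u-\bar u)(v-\bar v)}, with \eqn{w} the modulus
#' normalized to unit mass. For a real image the spectrum is point-symmetric
#' about DC, so the centroid is numerically zero.
#'
#' @param spec A `spectrum_distribution` (typically after [apply_cutoff()]).
#' @return A `moment_summary` with `total_mass`, `centroid` (u, v), `mu20`,
#'   `mu02`, `mu11` and covariance eigenvalues `lambda_major >= lambda_minor`.
#' @export
second_order_moments <- function(spec) {
  stopifnot(inherits(spec, "spectrum_distribution"))
  m <- spec$modulus
  tot <- sum(m)
  if (tot <= 0)
    stop_fibralign("spectrum has zero total mass",
                   "fibralign_degenerate_spectrum_error")
  u <- centered_coords(ncol(m))   # along columns (x frequency)
  v <- centered_coords(nrow(m))   # along rows (y frequency)
  wc <- colSums(m) / tot          # marginal over u
  wr <- rowSums(m) / tot          # marginal over v
  ubar <- sum(wc * u)
  vbar <- sum(wr * v)
  uc <- u - ubar
  vc <- v - vbar
  mu20 <- sum(wc * uc^2)
  mu02 <- sum(wr * vc^2)
  mu11 <- as.numeric(crossprod(vc, m %*% uc)) / tot
  tr <- mu20 + mu02
  disc <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  lam <- c((tr + disc) / 2, (tr - disc) / 2)
  structure(
    list(total_mass = tot, centroid = c(u = ubar, v = vbar),
         mu20 = mu20, mu02 = mu02, mu11 = mu11,
         lambda_major = lam[1], lambda_minor = max(0, lam[2])),
    class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf(
    "<moment_summary> mass %.4g; mu20 %.4g, mu02 %.4g, mu11 %.4g; lambda %.4g / %.4g\n",
    x$total_mass, x$mu20, x$mu02, x$mu11, x$lambda_major, x$lambda_minor))
  invisible(x)
}

#' Equivalent covariance ellipse of the spectrum
#'
#' The covariance matrix `[[mu20, mu11], [mu11, mu02]]` defines an equivalent
#' ellipse in the frequency domain. Its eccentricity
#' \eqn{\varepsilon = \sqrt{1 - \lambda_{min}/\lambda_{max}}} measures
#' alignment: 0 for an isotropic (randomly oriented) structure, approaching 1
#' for a totally aligned one. The long-axis direction is the orientation of
#' the major eigenvector, reported in degrees in `[0, 180)`.
#'
#' @param m A `moment_summary` from [second_order_moments()].
#' @return List with `eccentricity_eps` and `ellipse_angle_freq_deg`.
#' @export
equivalent_ellipse <- function(m) {
  stopifnot(inherits(m, "moment_summary"))
  if (m$lambda_major <= 0)
    stop_fibralign("all spectral mass at a single point: ellipse undefined",
                   "fibralign_degenerate_spectrum_error")
  eps <- sqrt(1 - m$lambda_minor / m$lambda_major)
  angle <- wrap180(0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02) * 180 / pi)
  list(eccentricity_eps = eps, ellipse_angle_freq_deg = angle)
}

#' Prevailing structure direction in image space
#'
#' A structure aligned along direction \eqn{\mu} in the image concentrates
#' its spectral energy along the perpendicular direction in the frequency
#' domain, so the shortest ellipse axis — perpendicular to the frequency
#' long axis — points along the spatial alignment direction.
#'
#' @param ellipse_angle_freq_deg Long-axis orientation of the frequency-domain
#'   ellipse, in degrees.
#' @return `mu_deg` in `[0, 180)`: the prevailing spatial direction.
#' @export
prevailing_direction <- function(ellipse_angle_freq_deg) {
  if (!is.finite(ellipse_angle_freq_deg))
    stop_fibralign("ellipse angle must be finite", "fibralign_parameter_error")
  wrap180(ellipse_angle_freq_deg + 90)
}
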