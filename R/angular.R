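#' Angular distribution of spectral sector sums
#'
#' Assigns every off-center pixel of the centered spectrum the angle
#' `atan2(v, u)` folded into the half-turn `[0, 180)` (antipodal pixels are
#' pooled, as Hermitian symmetry makes them redundant), sums the modulus over
#' `n_sectors` equal-width sectors, and normalizes the sector weights to sum
#' to 1. This is the normalized angular distribution that is subsequently
#' fitted with a normal to obtain the angular standard deviation.
#'
#' @param spec A `spectrum_distribution` with the DC term excluded (the angle
#'   is undefined at the origin; [apply_cutoff()] excludes it by default).
#' @param n_sectors Number of equal-width sectors over 180 degrees
#'   (default 180, i.e. 1-degree bins).
#' @return An `angular_distribution` with `bin_centers_deg`, `weights`
#'   (summing to 1), `n_sectors`, and—after [fit_angular_normal()]—
#'   `fit_mu_deg`, `fit_sigma_deg`.
#' @export
angular_sector_distribution <- function(spec, n_sectors = 180) {
  stopifnot(inherits(spec, "spectrum_distribution"))
  if (!is.numeric(n_sectors) || length(n_sectors) != 1 || n_sectors < 8)
    stop_fibralign("n_sectors must be an integer >= 8",
                   "fibralign_parameter_error")
  n_sectors <- as.integer(n_sectors)
  m <- spec$modulus
  h <- nrow(m); w <- ncol(m)
  m[dc_index(h), dc_index(w)] <- 0  # angle undefined at the origin
  tot <- sum(m)
  if (tot <= 0)
    stop_fibralign("spectrum has zero off-center mass",
                   "fibralign_degenerate_spectrum_error")
  u <- centered_coords(w)
  v <- centered_coords(h)
  ang <- wrap180(atan2(outer(v, rep(1, w)), outer(rep(1, h), u)) * 180 / pi)
  width <- 180 / n_sectors
  bin <- pmin(floor(ang / width) + 1, n_sectors)
  sums <- numeric(n_sectors)
  agg <- rowsum(as.vector(m), group = as.vector(bin))
  sums[as.integer(rownames(agg))] <- agg[, 1]
  structure(
    list(bin_centers_deg = (seq_len(n_sectors) - 0.5) * width,
         weights = sums / tot, n_sectors = n_sectors,
         fit_mu_deg = NA_real_, fit_sigma_deg = NA_real_),
    class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf("<angular_distribution> %d sectors", x$n_sectors))
  if (is.finite(x$fit_mu_deg))
    cat(sprintf("; fitted mu = %.2f deg, sigma = %.2f deg",
                x$fit_mu_deg, x$fit_sigma_deg))
  cat("\n")
  invisible(x)
}

#' Weighted normal fit of an angular distribution
#'
#' Orientations live on a half-turn circle (period 180 degrees), so a plain
#' normal fit is only well defined after unwrapping. The bins are re-centered
#' so the weighted circular mean sits mid-domain, removing wrap bias; the
#' fitted mean is the weighted mean of the re-centered angles mapped back to
#' `[0, 180)`, and the fitted sigma is the square root of the weighted sample
#' variance of the re-centered angles.
#'
#' @param dist An `angular_distribution` from [angular_sector_distribution()].
#' @return The distribution with `fit_mu_deg` (in `[0, 180)`) and
#'   `fit_sigma_deg` (in `[0, 90]` degrees) filled in.
#' @export
fit_angular_normal <- function(dist) {
  stopifnot(inherits(dist, "angular_distribution"))
  if (dist$n_sectors < 8)
    stop_fibralign("need at least 8 sectors to fit",
                   "fibralign_parameter_error")
  w <- dist$weights
  th <- dist$bin_centers_deg
  muc <- circular_mean180(th, w)
  # signed offsets from the circular mean, in (-90, 90]
  delta <- angdiff180(th, muc)
  mshift <- sum(w * delta)
  mu <- wrap180(muc + mshift)
  sigma <- sqrt(sum(w * (delta - mshift)^2))
  dist$fit_mu_deg <- mu
  dist$fit_sigma_deg <- sigma
  dist
}
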