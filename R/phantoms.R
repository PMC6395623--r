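#' Specification of a synthetic fibrous image
#'
#' Describes a phantom: straight, anti-aliased fiber segments with random
#' centers, orientations drawn from a wrapped-normal (aligned mats) or
#' uniform (isotropic control) model on the half-turn circle, over a uniform
#' background with additive Gaussian noise. The phantom provides ground-truth
#' orientation statistics against which the FFT pipeline is validated.
#'
#' @param image_px Square image side in pixels (default 825).
#' @param n_fibers Number of fibers (default 300).
#' @param orientation_model `"wrapped_normal"` or `"uniform"`.
#' @param mu0_deg Mean orientation in `[0, 180)` degrees (wrapped-normal).
#' @param sigma0_deg Orientation dispersion in degrees, > 0 (wrapped-normal).
#' @param length_px `c(mean, sd)` of fiber length in pixels.
#' @param width_px Fiber width in pixels (default 3).
#' @param fiber_intensity Fiber brightness in `(0, 1]` (default 0.8).
#' @param background Background level in `[0, 1)` (default 0.08).
#' @param noise_sd SD of additive Gaussian noise (default 0.02). Must satisfy
#'   `background + noise_sd < fiber_intensity`.
#' @param seed Integer RNG seed; identical specs render bit-identical images.
#' @return A `fiber_field_spec`.
#' @export
fiber_field_spec <- function(image_px = 825, n_fibers = 300,
                             orientation_model = c("wrapped_normal", "uniform"),
                             mu0_deg = 0, sigma0_deg = 10,
                             length_px = c(400, 80), width_px = 3,
                             fiber_intensity = 0.8, background = 0.08,
                             noise_sd = 0.02, seed = 1L) {
  orientation_model <- match.arg(orientation_model)
  if (orientation_model == "wrapped_normal") {
    if (!is.finite(sigma0_deg) || sigma0_deg <= 0)
      stop_fibralign("sigma0_deg must be > 0 for the wrapped-normal model",
                     "fibralign_parameter_error")
    mu0_deg <- wrap180(mu0_deg)
  }
  if (background + noise_sd >= fiber_intensity)
    stop_fibralign("fibers must be brighter than background + noise_sd",
                   "fibralign_parameter_error")
  structure(list(image_px = as.integer(image_px), n_fibers = as.integer(n_fibers),
                 orientation_model = orientation_model,
                 mu0_deg = mu0_deg, sigma0_deg = sigma0_deg,
                 length_px = length_px, width_px = width_px,
                 fiber_intensity = fiber_intensity, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fiber_field_spec")
}

#' Draw ground-truth fiber orientations
#'
#' Samples `n_fibers` orientations from the spec's model. The wrapped-normal
#' draws `mu0 + N(0, sigma0)` reduced modulo 180; the uniform model draws
#' from `[0, 180)`.
#'
#' @param spec A [fiber_field_spec()].
#' @return A `phantom_truth` with per-fiber `orientations_deg`, the
#'   generating parameters, and the seed.
#' @export
sample_orientations <- function(spec) {
  stopifnot(inherits(spec, "fiber_field_spec"))
  ang <- with_seed(spec$seed, {
    if (spec$orientation_model == "wrapped_normal")
      wrap180(spec$mu0_deg + stats::rnorm(spec$n_fibers, 0, spec$sigma0_deg))
    else
      stats::runif(spec$n_fibers, 0, 180)
  })
  structure(list(orientations_deg = ang,
                 orientation_model = spec$orientation_model,
                 mu0_deg = if (spec$orientation_model == "uniform") NA_real_
                           else spec$mu0_deg,
                 sigma0_deg = if (spec$orientation_model == "uniform") NA_real_
                              else spec$sigma0_deg,
                 seed = spec$seed),
            class = "phantom_truth")
}

#' Render a fibrous phantom image
#'
#' Draws each fiber as an anti-aliased straight segment (1-pixel linear
#' coverage ramp at the edges, sub-pixel endpoints) of the spec's width and
#' intensity at its sampled angle and a uniformly random center, composites
#' fibers by maximum, then adds the background and Gaussian noise and clips
#' to `[0, 1]`. Fully reproducible from `spec$seed`.
#'
#' @param truth A `phantom_truth` from [sample_orientations()].
#' @param spec The matching [fiber_field_spec()].
#' @return A [gray_image] of side `spec$image_px`.
#' @export
render_fiber_image <- function(truth, spec) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(spec, "fiber_field_spec"))
  n <- spec$n_fibers
  px <- spec$image_px
  img <- matrix(0, px, px)
  geom <- with_seed(spec$seed + 1L, {
    list(cx = stats::runif(n, 1, px), cy = stats::runif(n, 1, px),
         len = pmax(10, stats::rnorm(n, spec$length_px[1], spec$length_px[2])),
         noise = if (spec$noise_sd > 0) stats::rnorm(px * px, 0, spec$noise_sd)
                 else numeric(0))
  })
  half_w <- spec$width_px / 2
  for (k in seq_len(n)) {
    th <- truth$orientations_deg[k] * pi / 180
    dx <- cos(th); dy <- sin(th)
    hl <- geom$len[k] / 2
    p1x <- geom$cx[k] - hl * dx; p1y <- geom$cy[k] - hl * dy
    p2x <- geom$cx[k] + hl * dx; p2y <- geom$cy[k] + hl * dy
    margin <- half_w + 1.5
    c0 <- max(1L, floor(min(p1x, p2x) - margin))
    c1 <- min(px, ceiling(max(p1x, p2x) + margin))
    r0 <- max(1L, floor(min(p1y, p2y) - margin))
    r1 <- min(px, ceiling(max(p1y, p2y) + margin))
    if (c0 > c1 || r0 > r1) next
    xs <- c0:c1; ys <- r0:r1
    ex <- p2x - p1x; ey <- p2y - p1y
    L2 <- ex^2 + ey^2
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    t <- pmin(1, pmax(0, ((X - p1x) * ex + (Y - p1y) * ey) / L2))
    d <- sqrt((X - (p1x + t * ex))^2 + (Y - (p1y + t * ey))^2)
    cov <- pmin(1, pmax(0, half_w + 0.5 - d))
    blk <- img[ys, xs, drop = FALSE]
    img[ys, xs] <- pmax(blk, spec$fiber_intensity * cov)
  }
  img <- img + spec$background
  if (spec$noise_sd > 0) img <- img + geom$noise
  img[img < 0] <- 0
  img[img > 1] <- 1
  gray_image(img, source_id = sprintf("phantom_%s_seed%d",
                                      spec$orientation_model, spec$seed))
}

#' Generate a fibrous phantom in one call
#'
#' Convenience wrapper: [sample_orientations()] then [render_fiber_image()].
#'
#' @param spec A [fiber_field_spec()].
#' @return List with `image` ([gray_image]) and `truth` (`phantom_truth`).
#' @export
make_phantom <- function(spec) {
  truth <- sample_orientations(spec)
  list(image = render_fiber_image(truth, spec), truth = truth)
}

#' Write a benchmark grid of phantoms with ground truth
#'
#' Renders a fixed grid of phantoms — dispersion levels
#' `sigma0 in {5, 15, 30, 60} degrees` plus the uniform (isotropic) model,
#' crossed with mean orientations `mu0 in {0, 30, 90, 120}` degrees and
#' `replicates` seeds per cell — as 16-bit grayscale TIFFs in per-cell
#' subdirectories, plus a CSV manifest with the ground truth per file.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Base seed; per-file seeds are derived deterministically.
#' @param mu0_deg,sigma0_deg Grid levels (defaults as above).
#' @param include_uniform Add the uniform model as a fifth dispersion level.
#' @param replicates Phantoms per grid cell (default 3).
#' @param image_px,n_fibers,... Passed to [fiber_field_spec()].
#' @return Invisibly, the manifest data frame (columns `file`, `series`,
#'   `model`, `mu0_deg`, `sigma0_deg`, `n_fibers`, `seed`), also written to
#'   `out_dir/manifest.csv`.
#' @export
make_benchmark_suite <- function(out_dir, seed = 7L,
                                 mu0_deg = c(0, 30, 90, 120),
                                 sigma0_deg = c(5, 15, 30, 60),
                                 include_uniform = TRUE, replicates = 3,
                                 image_px = 825, n_fibers = 300, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop_fibralign(sprintf("cannot create directory %s", out_dir),
                   "fibralign_io_error")
  levels <- c(as.character(sigma0_deg), if (include_uniform) "uniform")
  rows <- list()
  i <- 0L
  for (mu0 in mu0_deg) {
    for (lev in levels) {
      series <- sprintf("mu%03d_%s", mu0,
                        if (lev == "uniform") "uniform"
                        else sprintf("s%02d", as.numeric(lev)))
      sdir <- file.path(out_dir, series)
      dir.create(sdir, showWarnings = FALSE)
      for (rep in seq_len(replicates)) {
        i <- i + 1L
        fseed <- as.integer(seed) + 101L * i
        spec <- if (lev == "uniform")
          fiber_field_spec(image_px = image_px, n_fibers = n_fibers,
                           orientation_model = "uniform", seed = fseed, ...)
        else
          fiber_field_spec(image_px = image_px, n_fibers = n_fibers,
                           orientation_model = "wrapped_normal",
                           mu0_deg = mu0, sigma0_deg = as.numeric(lev),
                           seed = fseed, ...)
        ph <- make_phantom(spec)
        fn <- file.path(sdir, sprintf("phantom_%03d.tif", i))
        tiff::writeTIFF(ph$image$pixels, fn, bits.per.sample = 16)
        rows[[i]] <- data.frame(
          file = fn, series = series,
          model = spec$orientation_model,
          mu0_deg = if (lev == "uniform") NA_real_ else mu0,
          sigma0_deg = if (lev == "uniform") NA_real_ else as.numeric(lev),
          n_fibers = n_fibers, seed = fseed, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
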