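# Small-scale phantom and config builders used across test files.
# 257 px keeps the full pipeline (including 64 px corner blocks) valid while
# staying fast; phantoms scale fiber geometry down accordingly.

small_config <- function(...) {
  analysis_config(crop_px = 257, corner_px = 64, ...)
}

small_phantom_spec <- function(model = "wrapped_normal", mu0 = 0, sigma0 = 10,
                               n_fibers = 80, seed = 1, noise_sd = 0.02,
                               width_px = 2, ...) {
  fiber_field_spec(image_px = 257, n_fibers = n_fibers,
                   orientation_model = model,
                   mu0_deg = mu0, sigma0_deg = sigma0,
                   length_px = c(120, 25), width_px = width_px,
                   noise_sd = noise_sd, seed = seed, ...)
}

# Exact 90-degree counterclockwise grid rotation.
rot90_mat <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Absolute circular distance between two orientations (period 180 degrees).
angdiff_deg <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}

# Bilinear resampled rotation about the image center (counterclockwise in
# x-right / y-down coordinates), used only to test rotation equivariance.
rot_bilinear <- function(m, angle_deg, fill = 0) {
  n <- nrow(m); w <- ncol(m)
  cy <- (n + 1) / 2; cx <- (w + 1) / 2
  th <- angle_deg * pi / 180
  out <- matrix(fill, n, w)
  xs <- rep(seq_len(w), each = n) - cx
  ys <- rep(seq_len(n), times = w) - cy
  # inverse map: source coords of each target pixel
  sx <- cos(th) * xs + sin(th) * ys + cx
  sy <- -sin(th) * xs + cos(th) * ys + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 1 & x0 < w & y0 >= 1 & y0 < n
  idx <- function(r, c) (c - 1L) * n + r
  v <- rep(fill, n * w)
  v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * m[idx(y0[ok], x0[ok])] +
    fx[ok] * (1 - fy[ok]) * m[idx(y0[ok], x0[ok] + 1L)] +
    (1 - fx[ok]) * fy[ok] * m[idx(y0[ok] + 1L, x0[ok])] +
    fx[ok] * fy[ok] * m[idx(y0[ok] + 1L, x0[ok] + 1L)]
  out[] <- v
  out
}
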