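# Small numeric helpers shared across the package.

#' Round half away from zero
#'
#' Deterministic decimal rounding in which exact halves round up (for positive
#' numbers), matching how quantities such as percentages and fold-changes are
#' conventionally reported. Base [round()] uses banker's rounding, which would
#' turn e.g. 0.25 into 0.2.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(c(35.769, 9.4054, 1.405), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # tiny nudge guards against halves stored just below .5 in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Index of the DC (zero-frequency) pixel after centering, for one axis of
# length n: odd n gives the true center, even n places DC at floor(n/2)+1.
dc_index <- function(n) floor(n / 2) + 1L

# Centered integer frequency coordinates for an axis of length n.
centered_coords <- function(n) seq_len(n) - dc_index(n)

# fftshift permutation for one axis: moves DC from index 1 to dc_index(n).
fftshift_idx <- function(n) ((seq_len(n) - 1L + (n - floor(n / 2))) %% n) + 1L

# Reduce an angle in degrees to the orientation half-turn [0, 180).
wrap180 <- function(theta_deg) theta_deg %% 180

# Circular mean of orientations (period 180 degrees), weighted.
circular_mean180 <- function(theta_deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta_deg))
  z <- sum(w * exp(2i * theta_deg * pi / 180))
  wrap180(Arg(z) * 180 / pi / 2)
}

# Smallest signed difference between two orientations, in (-90, 90].
angdiff180 <- function(a_deg, b_deg) {
  d <- (a_deg - b_deg) %% 180
  ifelse(d > 90, d - 180, d)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library calls do not perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_fibralign <- function(msg, class) {
  stop(structure(class = c(class, "fibralign_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
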