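# Independent brute-force oracles. These deliberately use plain double loops
# and none of the package's vectorised code paths.

# O(N^2 M^2) direct 2D DFT modulus, uncentered (DC at [1,1]).
dft2_modulus_brute <- function(x) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (p in 0:(h - 1)) {
    for (q in 0:(w - 1)) {
      acc <- 0 + 0i
      for (m in 0:(h - 1)) {
        for (n in 0:(w - 1)) {
          acc <- acc + x[m + 1, n + 1] *
            exp(-2i * pi * (p * m / h + q * n / w))
        }
      }
      out[p + 1, q + 1] <- Mod(acc)
    }
  }
  out
}

# Centering permutation written independently: rotate so that the DC entry
# lands at (floor(h/2)+1, floor(w/2)+1).
center_brute <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in 1:h) {
    for (j in 1:w) {
      # uncentered index (i,j) holds frequency (i-1, j-1); wrap to signed
      fi <- i - 1; if (fi > h - floor(h / 2) - 1) fi <- fi - h
      fj <- j - 1; if (fj > w - floor(w / 2) - 1) fj <- fj - w
      out[fi + floor(h / 2) + 1, fj + floor(w / 2) + 1] <- m[i, j]
    }
  }
  out
}

# Second-order central moments by explicit double loop over every pixel.
moments_brute <- function(m) {
  h <- nrow(m); w <- ncol(m)
  tot <- sum(m)
  ubar <- 0; vbar <- 0
  for (i in 1:h) for (j in 1:w) {
    u <- j - (floor(w / 2) + 1); v <- i - (floor(h / 2) + 1)
    ubar <- ubar + m[i, j] * u / tot
    vbar <- vbar + m[i, j] * v / tot
  }
  mu20 <- 0; mu02 <- 0; mu11 <- 0
  for (i in 1:h) for (j in 1:w) {
    u <- j - (floor(w / 2) + 1) - ubar
    v <- i - (floor(h / 2) + 1) - vbar
    mu20 <- mu20 + m[i, j] * u^2 / tot
    mu02 <- mu02 + m[i, j] * v^2 / tot
    mu11 <- mu11 + m[i, j] * u * v / tot
  }
  list(ubar = ubar, vbar = vbar, mu20 = mu20, mu02 = mu02, mu11 = mu11)
}

# Per-pixel angular binning by explicit loop.
sector_sums_brute <- function(m, n_sectors) {
  h <- nrow(m); w <- ncol(m)
  sums <- numeric(n_sectors)
  width <- 180 / n_sectors
  for (i in 1:h) for (j in 1:w) {
    u <- j - (floor(w / 2) + 1); v <- i - (floor(h / 2) + 1)
    if (u == 0 && v == 0) next
    a <- (atan2(v, u) * 180 / pi) %% 180
    b <- min(floor(a / width) + 1, n_sectors)
    sums[b] <- sums[b] + m[i, j]
  }
  sums
}

# Exhaustive scan over the four corner blocks of a centered matrix.
corner_max_brute <- function(m, corner_px) {
  h <- nrow(m); w <- ncol(m)
  best <- -Inf
  for (i in 1:h) for (j in 1:w) {
    in_r <- i <= corner_px || i > h - corner_px
    in_c <- j <= corner_px || j > w - corner_px
    if (in_r && in_c) best <- max(best, m[i, j])
  }
  best
}

# Wrap a raw modulus matrix as a spectrum_distribution for unit tests.
make_spec <- function(m) {
  structure(list(modulus = m, cutoff = 0, dc_excluded = FALSE, dim = dim(m),
                 source_id = "test"),
            class = "spectrum_distribution")
}
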