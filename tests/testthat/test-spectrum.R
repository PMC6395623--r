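test_that("constant image has all spectral mass at the centered DC pixel", {
  n <- 9
  s <- compute_spectrum(gray_image(matrix(0.4, n, n)))
  expect_equal(s$modulus[5, 5], 0.4 * n^2, tolerance = 1e-10)
  off <- s$modulus; off[5, 5] <- 0
  expect_lt(max(off), 1e-8)
})

test_that("centered modulus of a real image is point-symmetric about DC", {
  set.seed(42)
  for (n in c(9, 16, 25)) {
    m <- compute_spectrum(matrix(runif(n * n), n, n))$modulus
    flipped <- m[nrow(m):1, ncol(m):1]
    # for odd n the reversal fixes the center; for even n the first
    # (unmatched Nyquist) row/column must be dropped before comparing
    if (n %% 2 == 0) {
      m2 <- m[-1, -1]; f2 <- flipped[-nrow(m), -ncol(m)]
    } else {
      m2 <- m; f2 <- flipped
    }
    expect_equal(m2, f2, tolerance = 1e-8)
  }
})

test_that("spectrum matches a brute-force O(N^4) DFT on small images", {
  set.seed(7)
  x <- cos(2 * pi * 2 * (0:8) / 9)          # single cosine along x
  img <- matrix(x, 9, 9, byrow = TRUE)      # varies along columns only
  img <- img - min(img) + 0.1
  got <- compute_spectrum(img)$modulus
  want <- center_brute(dft2_modulus_brute(img))
  expect_equal(got, want, tolerance = 1e-8)
  # off-DC mass of a horizontal cosine sits on the horizontal frequency axis
  off <- got; off[5, 5] <- 0
  expect_gt(sum(off[5, ]), 0.999 * sum(off))
  # and a fully random image agrees with the oracle too
  r <- matrix(runif(81), 9, 9)
  expect_equal(compute_spectrum(r)$modulus,
               center_brute(dft2_modulus_brute(r)), tolerance = 1e-8)
})

test_that("non-finite pixels are rejected", {
  m <- matrix(1, 9, 9); m[3, 3] <- Inf
  expect_error(compute_spectrum(m), class = "fibralign_input_error")
})

test_that("noise cutoff is the maximum over the four corner blocks", {
  set.seed(11)
  m <- matrix(runif(31 * 31, 0, 5), 31, 31)
  m[2, 3] <- 7.5  # planted corner maximum
  s <- make_spec(m)
  expect_equal(estimate_noise_cutoff(s, corner_px = 6), 7.5)
  expect_equal(estimate_noise_cutoff(s, corner_px = 6),
               corner_max_brute(m, 6))
  expect_equal(estimate_noise_cutoff(make_spec(matrix(1, 31, 31)), 6), 1)
  z <- m; z[c(1:6, 26:31), c(1:6, 26:31)] <- 0
  expect_equal(estimate_noise_cutoff(make_spec(z), 6), 0)
})

test_that("corner blocks may not reach the center", {
  s <- make_spec(matrix(1, 31, 31))
  expect_error(estimate_noise_cutoff(s, corner_px = 15),
               class = "fibralign_parameter_error")
})

test_that("apply_cutoff zeroes sub-threshold values and optionally DC", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  s <- apply_cutoff(make_spec(m), 0, exclude_dc = FALSE)
  expect_equal(s$modulus, m)                      # identity at cutoff 0
  s <- apply_cutoff(make_spec(m), 2.5, exclude_dc = FALSE)
  expect_equal(sum(s$modulus > 0), sum(m >= 2.5)) # brute survivor count
  expect_true(all(s$modulus[s$modulus > 0] >= 2.5))
  s <- apply_cutoff(make_spec(m), 0, exclude_dc = TRUE)
  expect_equal(s$modulus[2, 2], 0)
  expect_true(s$dc_excluded)
})

test_that("a constant image dies at the cutoff stage when DC is excluded", {
  spec <- compute_spectrum(gray_image(matrix(0.5, 33, 33)))
  expect_error(apply_cutoff(spec, 0, exclude_dc = TRUE),
               class = "fibralign_degenerate_spectrum_error")
})

test_that("log display normalization maps to [0,1] and preserves rank order", {
  expect_equal(log_display_normalize(make_spec(matrix(3, 5, 5))),
               matrix(0, 5, 5), ignore_attr = TRUE)
  two <- log_display_normalize(make_spec(matrix(c(0, exp(1) - 1), 1, 2)))
  expect_equal(as.vector(two), c(0, 1), tolerance = 1e-12)
  set.seed(3)
  m <- matrix(rexp(100), 10, 10)
  g <- log_display_normalize(make_spec(m))
  expect_true(all(g >= 0 & g <= 1))
  expect_equal(order(as.vector(g)), order(as.vector(m)))
})
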