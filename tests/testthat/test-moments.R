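test_that("moments match an independent double-loop summation", {
  set.seed(5)
  for (dims in list(c(7, 7), c(15, 15), c(9, 12))) {
    m <- matrix(runif(prod(dims)), dims[1], dims[2])
    got <- second_order_moments(make_spec(m))
    want <- moments_brute(m)
    expect_equal(unname(got$centroid), c(want$ubar, want$vbar),
                 tolerance = 1e-12)
    expect_equal(got$mu20, want$mu20, tolerance = 1e-12)
    expect_equal(got$mu02, want$mu02, tolerance = 1e-12)
    expect_equal(got$mu11, want$mu11, tolerance = 1e-12)
    expect_gte(got$lambda_major, got$lambda_minor)
    expect_gte(got$mu20 * got$mu02 - got$mu11^2, -1e-12)
  }
})

test_that("an isotropic Gaussian-shaped modulus gives a circular ellipse", {
  u <- centered <- -10:10
  m <- exp(-outer(u^2, u^2, "+") / 18)
  mom <- second_order_moments(make_spec(m))
  expect_equal(mom$mu20, mom$mu02, tolerance = 1e-10)
  expect_equal(mom$mu11, 0, tolerance = 1e-10)
  expect_equal(equivalent_ellipse(mom)$eccentricity_eps, 0, tolerance = 1e-6)
})

test_that("mass confined to the central row degenerates to a line", {
  m <- matrix(0, 11, 11); m[6, ] <- runif(11) + 0.5
  mom <- second_order_moments(make_spec(m))
  expect_equal(mom$mu02, 0)
  expect_equal(mom$mu11, 0)
  expect_equal(mom$lambda_minor, 0)
  ell <- equivalent_ellipse(mom)
  expect_equal(ell$eccentricity_eps, 1)
  expect_equal(ell$ellipse_angle_freq_deg, 0)
})

test_that("eccentricity and angle follow the closed-form eigendecomposition", {
  mk <- function(mu20, mu02, mu11) {
    structure(list(total_mass = 1, centroid = c(u = 0, v = 0),
                   mu20 = mu20, mu02 = mu02, mu11 = mu11,
                   lambda_major = max((mu20 + mu02) / 2 +
                     sqrt((mu20 - mu02)^2 + 4 * mu11^2) / 2, 0),
                   lambda_minor = max((mu20 + mu02) / 2 -
                     sqrt((mu20 - mu02)^2 + 4 * mu11^2) / 2, 0)),
              class = "moment_summary")
  }
  # mu20 = 3, mu02 = 1, mu11 = 0: eigenvalues 3 and 1 by inspection
  e <- equivalent_ellipse(mk(3, 1, 0))
  expect_equal(e$eccentricity_eps, sqrt(1 - 1 / 3), tolerance = 1e-12)
  expect_equal(e$ellipse_angle_freq_deg, 0)
  expect_equal(equivalent_ellipse(mk(2, 2, 0))$eccentricity_eps, 0)
  # equal diagonal with positive cross term: major axis at 45 degrees
  e45 <- equivalent_ellipse(mk(2, 2, 1))
  expect_equal(e45$ellipse_angle_freq_deg, 45, tolerance = 1e-10)
  expect_equal(e45$eccentricity_eps, sqrt(1 - 1 / 3), tolerance = 1e-12)
  expect_error(equivalent_ellipse(mk(0, 0, 0)),
               class = "fibralign_degenerate_spectrum_error")
})

test_that("prevailing direction is perpendicular to the frequency long axis", {
  expect_equal(prevailing_direction(0), 90)
  expect_equal(prevailing_direction(90), 0)
  expect_equal(prevailing_direction(170), 80)
  for (a in seq(0, 179, by = 17))
    expect_equal((prevailing_direction(a) - a) %% 180, 90, tolerance = 1e-9)
  expect_error(prevailing_direction(NaN), class = "fibralign_parameter_error")
})

test_that("spectral centroid of a real image is at the origin", {
  set.seed(9)
  for (n in c(15, 25)) {
    spec <- compute_spectrum(matrix(runif(n * n), n, n))
    mom <- second_order_moments(spec)
    expect_lt(sqrt(sum(mom$centroid^2)), 1e-6 * (n / 2))
  }
  # even sizes carry an unpaired Nyquist row/column: small but nonzero shift
  spec <- compute_spectrum(matrix(runif(24 * 24), 24, 24))
  expect_lt(sqrt(sum(second_order_moments(spec)$centroid^2)), 1)
})
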