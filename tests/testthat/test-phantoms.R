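test_that("orientation sampling is reproducible and respects the model", {
  sp <- small_phantom_spec(mu0 = 40, sigma0 = 8, seed = 5)
  t1 <- sample_orientations(sp)
  t2 <- sample_orientations(sp)
  expect_identical(t1$orientations_deg, t2$orientations_deg)
  expect_true(all(t1$orientations_deg >= 0 & t1$orientations_deg < 180))
  # vanishing dispersion collapses to the mean orientation
  sp0 <- small_phantom_spec(mu0 = 73, sigma0 = 1e-6, seed = 2)
  expect_true(all(abs(sample_orientations(sp0)$orientations_deg - 73) < 1e-4))
})

test_that("uniform orientations have a tiny circular resultant at large n", {
  sp <- fiber_field_spec(image_px = 257, n_fibers = 1e5,
                         orientation_model = "uniform", seed = 3)
  th <- sample_orientations(sp)$orientations_deg
  R <- Mod(sum(exp(2i * th * pi / 180))) / length(th)
  expect_lt(R, 0.02)
})

test_that("spec invariants are enforced", {
  expect_error(fiber_field_spec(orientation_model = "wrapped_normal",
                                sigma0_deg = 0),
               class = "fibralign_parameter_error")
  expect_error(fiber_field_spec(background = 0.5, noise_sd = 0.4,
                                fiber_intensity = 0.8),
               class = "fibralign_parameter_error")
})

test_that("rendering is bit-identical under an identical spec and seed", {
  sp <- small_phantom_spec(seed = 9)
  a <- make_phantom(sp)$image
  b <- make_phantom(sp)$image
  expect_identical(a$pixels, b$pixels)
  sp2 <- small_phantom_spec(seed = 10)
  expect_false(identical(make_phantom(sp2)$image$pixels, a$pixels))
})

test_that("a single noiseless horizontal fiber is recovered at 0 degrees", {
  sp <- fiber_field_spec(image_px = 257, n_fibers = 1,
                         orientation_model = "wrapped_normal",
                         mu0_deg = 0, sigma0_deg = 1e-6,
                         length_px = c(180, 0), width_px = 2,
                         noise_sd = 0, background = 0.05, seed = 4)
  r <- analyze_image(make_phantom(sp)$image, small_config())
  expect_lt(abs(angdiff_deg(r$mu_deg, 0)), 2)
  expect_gt(r$eccentricity_eps, 0.9)
})

test_that("an aligned mat is more eccentric than an isotropic one", {
  ra <- analyze_image(make_phantom(small_phantom_spec(
    model = "wrapped_normal", mu0 = 30, sigma0 = 5,
    n_fibers = 150, seed = 6))$image, small_config())
  ri <- analyze_image(make_phantom(small_phantom_spec(
    model = "uniform", n_fibers = 150, seed = 6))$image, small_config())
  expect_gt(ra$eccentricity_eps, ri$eccentricity_eps)
  expect_gt(ra$eccentricity_eps, 0.9)   # near-parallel fibers
  expect_lt(ra$sigma_deg, ri$sigma_deg)
})

test_that("rendered fibers stand out from the noise floor", {
  sp <- small_phantom_spec(seed = 12)
  ph <- make_phantom(sp)
  img <- ph$image$pixels
  fiber_px <- img > sp$background + 0.5 * sp$fiber_intensity
  expect_gt(mean(img[fiber_px]) - sp$background, 3 * sp$noise_sd)
  expect_gt(sum(fiber_px), 0)
})

test_that("an empty fiber field analyzes as unreliable or degenerate", {
  sp <- fiber_field_spec(image_px = 257, n_fibers = 0,
                         orientation_model = "uniform",
                         noise_sd = 0.02, seed = 8)
  img <- make_phantom(sp)$image
  res <- tryCatch(analyze_image(img, small_config()), error = identity)
  if (inherits(res, "error")) {
    expect_s3_class(res, "fibralign_degenerate_spectrum_error")
  } else {
    expect_true(length(res$flags) > 0)  # unreliable and/or noise-only
  }
})

test_that("benchmark suite writes the full grid with a faithful manifest", {
  out <- file.path(tempdir(), "bench_small")
  unlink(out, recursive = TRUE)
  man <- make_benchmark_suite(out, seed = 3, replicates = 1,
                              image_px = 129, n_fibers = 30,
                              length_px = c(60, 12), width_px = 2)
  expect_equal(nrow(man), 4 * 5)
  expect_true(all(file.exists(man$file)))
  expect_equal(length(unique(man$series)), 20)
  expect_true(all(is.na(man$mu0_deg[man$model == "uniform"])))
  # regeneration under the same seed reproduces the manifest byte-for-byte
  csv1 <- readLines(file.path(out, "manifest.csv"))
  man2 <- make_benchmark_suite(out, seed = 3, replicates = 1,
                               image_px = 129, n_fibers = 30,
                               length_px = c(60, 12), width_px = 2)
  expect_identical(readLines(file.path(out, "manifest.csv")), csv1)
  # a written phantom decodes to the rendered image (16-bit quantization)
  img <- load_and_prepare(man$file[1], crop_px = 129)
  spec <- fiber_field_spec(image_px = 129, n_fibers = 30,
                           orientation_model = man$model[1],
                           mu0_deg = ifelse(is.na(man$mu0_deg[1]), 0,
                                            man$mu0_deg[1]),
                           sigma0_deg = ifelse(is.na(man$sigma0_deg[1]), 10,
                                               man$sigma0_deg[1]),
                           length_px = c(60, 12), width_px = 2,
                           seed = man$seed[1])
  expect_lt(max(abs(img$pixels - make_phantom(spec)$image$pixels)),
            1 / 65535)
  unlink(out, recursive = TRUE)
})
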