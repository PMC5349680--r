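test_that("templates are peak-normalized, symmetric in wavenumber, and decay", {
  for (fam in c("gaussian_wavenumber", "govardovskii_A1", "govardovskii_A2")) {
    tpl <- pigment_template("t", 522, family = fam)
    expect_equal(template_absorbance(522, tpl), 1, info = fam)
  }
  tpl <- pigment_template("rh", 522)
  delta <- 2e-5
  lhs <- template_absorbance(1 / (1 / 522 + delta), tpl)
  rhs <- template_absorbance(1 / (1 / 522 - delta), tpl)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_lt(template_absorbance(750, tpl), 0.01)
  g <- seq(350, 750, 1)
  expect_true(all(template_absorbance(g, tpl) >= 0))
  expect_true(all(template_absorbance(g, tpl) <= 1 + 1e-12))
})

test_that("spectrum composition is linear with a flat-baseline zero case", {
  grid <- seq(350, 750, by = 1)
  tpls <- cone_pigment_templates()
  one <- compose_spectrum(c(red = 1), tpls, baseline = 0, grid = grid)
  expect_equal(one, template_absorbance(grid, tpls[[1]]))
  amts <- c(red = 0.4, green = 0.9, blue = 0.2)
  s1 <- compose_spectrum(amts, tpls, baseline = 0.1, grid = grid)
  s2 <- compose_spectrum(2 * amts, tpls, baseline = 0.1, grid = grid)
  expect_equal(s2 - 0.1, 2 * (s1 - 0.1), tolerance = 1e-12)
  flat <- compose_spectrum(c(red = 0), tpls, baseline = 0.25, grid = grid)
  expect_equal(flat, rep(0.25, length(grid)))
  expect_error(compose_spectrum(c(red = -1), tpls, grid = grid),
               "non-negative")
})

test_that("difference spectra subtract pointwise and are antisymmetric", {
  a <- c(1, 2, 3); b <- c(0.5, 1.5, 3)
  expect_equal(difference_spectrum(a, a), c(0, 0, 0))
  expect_equal(difference_spectrum(a, b), -difference_spectrum(b, a))
  expect_error(difference_spectrum(a, b[1:2]), "grid")
})

test_that("sequential bleaching recovers cone pigment contents exactly", {
  grid <- seq(350, 750, by = 1)  # contains 622, 535, 460
  tpls <- cone_pigment_templates()
  amts <- c(red = 0.8, green = 1.3, blue = 0.45)
  series <- simulate_bleach_series(amts, tpls, noise_sigma = 0,
                                   baseline = 0.05, grid = grid)
  steps <- lapply(seq_along(amts), function(k) bleach_step(k, names(amts)[k]))
  got <- quantify_sequential_bleach(series, steps, tpls)
  expect_equal(got$content, unname(amts), tolerance = 1e-12)
  expect_equal(got$peak_wavelength, c(622, 535, 460))
  # fit-mode and peak-mode agree on noiseless single-component differences
  fit <- quantify_sequential_bleach(series, steps, tpls, mode = "fit")
  expect_equal(fit$content, got$content, tolerance = 1e-10)
})

test_that("a single-pigment rod series recovers its coefficient at 522 nm", {
  grid <- seq(350, 750, by = 1)
  rh <- list(pigment_template("rhodopsin", 522))
  series <- simulate_bleach_series(c(rhodopsin = 2.2), rh, noise_sigma = 0,
                                   grid = grid)
  got <- quantify_sequential_bleach(series,
                                    list(bleach_step(1, "rhodopsin")), rh)
  expect_equal(got$content, 2.2, tolerance = 1e-12)
  expect_equal(got$peak_wavelength, 522)
})

test_that("an incomplete bleach under-reports content proportionally", {
  grid <- seq(350, 750, by = 1)
  rh <- list(pigment_template("rhodopsin", 522))
  series <- simulate_bleach_series(
    c(rhodopsin = 2), rh,
    steps = list(bleach_step(1, "rhodopsin", completeness = 0.5)),
    noise_sigma = 0, grid = grid)
  got <- quantify_sequential_bleach(series,
                                    list(bleach_step(1, "rhodopsin")), rh)
  expect_equal(got$content, 1, tolerance = 1e-12)
})

test_that("content error under additive noise stays within 5 sigma", {
  grid <- seq(350, 750, by = 2)
  tpls <- cone_pigment_templates()
  amts <- c(red = 0.8, green = 1.3, blue = 0.45)
  steps <- lapply(seq_along(amts), function(k) bleach_step(k, names(amts)[k]))
  sigma <- 0.01
  errs <- vapply(1:200, function(s) {
    series <- simulate_bleach_series(amts, tpls, noise_sigma = sigma,
                                     grid = grid, seed = s)
    got <- quantify_sequential_bleach(series, steps, tpls)
    max(abs(got$content - unname(amts)))
  }, numeric(1))
  expect_gte(mean(errs < 5 * sigma), 0.95)
})

test_that("curve-count and grid mismatches are rejected", {
  grid <- seq(400, 700, by = 5)
  rh <- list(pigment_template("rhodopsin", 522))
  series <- simulate_bleach_series(c(rhodopsin = 1), rh, grid = grid)
  steps2 <- list(bleach_step(1, "rhodopsin"), bleach_step(2, "rhodopsin"))
  expect_error(quantify_sequential_bleach(series, steps2, rh), "curves")
})

test_that("pigment recovery mirrors marker recovery semantics", {
  expect_equal(pigment_recovery(0.862 * 3, 3), 86.2)
  expect_equal(pigment_recovery(0, 3), 0)
  expect_error(pigment_recovery(1, 0), "positive")
})
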