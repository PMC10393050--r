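test_that("Faraday rotation is the product V*B*L and multilinear", {
  expect_identical(faraday_rotation(1, 1, 1), 1)
  expect_identical(faraday_rotation(1, 0, 1), 0)
  expect_identical(faraday_rotation(2, 150, 3), 900)
  set.seed(11)
  for (i in 1:20) {
    v <- runif(1, 0.1, 10); b <- runif(1, 0.1, 300); l <- runif(1, 0.1, 5)
    expect_equal(faraday_rotation(2 * v, b, l), 2 * faraday_rotation(v, b, l))
    expect_equal(faraday_rotation(v, 3 * b, l), 3 * faraday_rotation(v, b, l))
    expect_equal(faraday_rotation(v, b, 5 * l), 5 * faraday_rotation(v, b, l))
  }
  expect_error(faraday_rotation(NaN, 1, 1), "finite")
  expect_error(faraday_rotation(1, 1, -1), "> 0")
})

test_that("birefringence form gives pi*L*B*dn/lambda", {
  expect_equal(faraday_rotation_birefringence(1, 1, 532, 532), pi)
  expect_equal(faraday_rotation_birefringence(3, 2, 0, 532), 0)
  expect_equal(faraday_rotation_birefringence(2, 1, 532, 532), 2 * pi)
  expect_error(faraday_rotation_birefringence(1, 1, 1, 0), "> 0")
})

test_that("Verdet constant inverts the rotation and handles the field angle", {
  expect_equal(verdet_constant(2, 1, 2, 0), 1)
  expect_equal(verdet_constant(1, 1, 2, pi / 3), 1)  # cos(pi/3) = 0.5
  set.seed(12)
  for (i in 1:25) {
    v <- runif(1, 0.01, 10); b <- runif(1, 0.1, 300); l <- runif(1, 0.1, 5)
    expect_equal(verdet_constant(faraday_rotation(v, b, l), l, b, 0), v,
                 tolerance = 1e-12)
  }
  expect_error(verdet_constant(1, 1, 2, pi / 2), "degenerate")
  expect_error(verdet_constant(1, 1, 0, 0), "degenerate")
})

test_that("minimal decorrelation field scales as k*pi*L/(R*phi)", {
  expect_equal(min_decorrelation_field(1, 1, 1, 1), pi)
  expect_equal(min_decorrelation_field(2, 1, 1, 1), 2 * pi)
  expect_equal(min_decorrelation_field(1, 2, pi, 1), 0.5)
  # monotonicity: decreasing in R and phi, increasing in L
  expect_lt(min_decorrelation_field(1, 4, 1), min_decorrelation_field(1, 2, 1))
  expect_lt(min_decorrelation_field(1, 1, 3), min_decorrelation_field(1, 1, 2))
  expect_gt(min_decorrelation_field(3, 1, 1), min_decorrelation_field(2, 1, 1))
  expect_error(min_decorrelation_field(1, 0, 1), "degenerate")
})

test_that("Beer-Lambert absorbance, reflection doubling and monotonicity", {
  out <- beer_lambert(attenuation_params(1, 1, 1, 1))
  expect_equal(out$absorbance, 1)
  expect_equal(out$transmitted_intensity, exp(-1), tolerance = 1e-12)
  refl <- beer_lambert(attenuation_params(1, 1, 1, 1, reflection_mode = TRUE))
  expect_equal(refl$absorbance, 2)
  expect_equal(refl$transmitted_intensity, exp(-2), tolerance = 1e-12)
  none <- beer_lambert(attenuation_params(0, 2, 3, 5))
  expect_equal(none$absorbance, 0)
  expect_equal(none$transmitted_intensity, 5)
  # transmitted in (0, I0], monotone decreasing in eps, C, d
  set.seed(13)
  for (i in 1:15) {
    e <- runif(1, 0, 2); cc <- runif(1, 0, 2); d <- runif(1, 0, 2)
    t0 <- beer_lambert(attenuation_params(e, cc, d))$transmitted_intensity
    expect_gt(t0, 0); expect_lte(t0, 1)
    expect_lte(beer_lambert(attenuation_params(e + 0.5, cc, d))$transmitted_intensity, t0)
    expect_lte(beer_lambert(attenuation_params(e, cc + 0.5, d))$transmitted_intensity, t0)
    expect_lte(beer_lambert(attenuation_params(e, cc, d + 0.5))$transmitted_intensity, t0)
  }
  expect_error(attenuation_params(-1, 1, 1), ">= 0")
})
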