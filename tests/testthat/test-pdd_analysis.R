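test_that("sigma/DFW conversions apply the 1.13 bookkeeping exactly and invert", {
  expect_equal(sigma_from_dfw(0.24), 2.4 / 1.13, tolerance = 1e-12)
  expect_equal(sigma_from_dfw(0.24), 2.12, tolerance = 0.005)
  expect_equal(sigma_from_dfw(0.40), 3.54, tolerance = 0.005)
  expect_equal(sigma_from_dfw(0), 0)
  # exact mutual inverses across a sweep
  for (d in c(0.01, 0.24, 0.36, 0.48, 1.3)) {
    expect_equal(dfw_from_sigma(sigma_from_dfw(d)), d, tolerance = 1e-12)
  }
  expect_equal(sigma_from_dfw(0.48), 4.8 / 1.13, tolerance = 1e-12)
  # printed as 4.24; direct division gives 4.248
})

test_that("quadrature subtraction reproduces printed heterogeneity sigmas and round-trips", {
  expect_equal(sigma_hetero_quadrature(3.53, 2.12), 2.82, tolerance = 0.005)
  expect_equal(sigma_hetero_quadrature(4.24, 3.13), 2.86, tolerance = 0.005)
  expect_equal(sigma_hetero_quadrature(5, 0), 5)
  expect_error(sigma_hetero_quadrature(2.0, 2.1), "negative")
  set.seed(1)
  for (i in 1:25) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5)
    expect_equal(sigma_hetero_quadrature(sqrt(a^2 + b^2), a), b,
                 tolerance = 1e-9)
  }
})

test_that("closed-form binomial heterogeneity sigma matches its printed values and limits", {
  expect_equal(sigma_theory(0.237, 4, 0.4), 1.70, tolerance = 0.005)
  expect_equal(sigma_theory(0.237, 4, 1.6), 3.40, tolerance = 0.005)
  expect_lt(sigma_theory(1e-12, 4, 0.4), 1e-4)
  expect_lt(sigma_theory(1 - 1e-12, 4, 0.4), 1e-4)
  expect_error(sigma_theory(1.2, 4, 0.4), "p must")
  expect_error(sigma_theory(0, 4, 0.4), "p must")
})

test_that("Monte Carlo column oracle agrees with the closed form", {
  # hand-computable case: 10 segments of 1 mm at p = 0.5 -> sqrt(10/4)
  s <- binomial_column_oracle(0.5, 1, 1, 4e4, seed = 2)
  expect_equal(s, sqrt(10 * 0.25), tolerance = 0.02)
  expect_equal(binomial_column_oracle(1, 1, 1, 1000, seed = 3), 0)
  # 3 x 3 grid of (p, delta): within 3 standard errors of sd(sigma)
  n_col <- 2e4
  for (p in c(0.1, 0.237, 0.6)) {
    for (delta in c(0.4, 0.8, 1.6)) {
      s <- binomial_column_oracle(p, 4, delta, n_col, seed = 17)
      th <- sigma_theory(p, 4, delta)
      se <- th / sqrt(2 * (n_col - 1))  # sd of a sample sd, normal approx
      expect_lt(abs(s - th), 3.5 * se)
    }
  }
  expect_error(binomial_column_oracle(0.3, 1, 0.3, 100, 1), "integer")
})

test_that("distal falloff of a Gaussian edge is 1.6832 sigma, not 1.13 sigma", {
  z <- seq(0, 10, by = 0.02)
  for (sig_mm in c(1, 2, 3, 5)) {
    sig <- sig_mm / 10
    curve <- depth_dose_curve(z, stats::pnorm((6 - z) / sig))
    expect_equal(compute_dfw(curve), erfc_edge_width_factor * sig,
                 tolerance = 0.01 / (erfc_edge_width_factor * sig))
  }
  expect_equal(erfc_edge_width_factor, 1.6832, tolerance = 1e-4)
})

test_that("falloff width of a step edge collapses to one grid bin", {
  z <- seq(0, 4, by = 0.02)
  d <- as.numeric(z < 2)
  expect_lte(compute_dfw(depth_dose_curve(z, d)), 0.02)
})

test_that("falloff crossings interpolate linearly and fail on truncated tails", {
  # triangle peak with linear distal edge: crossings computable by hand
  z <- seq(0, 2, by = 0.02)
  d <- pmax(0, pmin(z, 2 - z))  # peak 1 at z = 1, linear down to 0 at z = 2
  # distal: dose = 2 - z; 80% at z = 1.2, 20% at z = 1.8
  expect_equal(compute_dfw(depth_dose_curve(z, d)), 0.6, tolerance = 1e-9)
  trunc <- depth_dose_curve(z[z <= 1.5], d[z <= 1.5])
  expect_error(compute_dfw(trunc), "truncated")
})

test_that("peak value is a percentage of the pristine maximum", {
  z <- seq(0, 2, by = 0.02)
  c1 <- depth_dose_curve(z, exp(-(z - 1)^2))
  expect_equal(peak_value(c1, c1), 100)
  c2 <- depth_dose_curve(z, 0.5 * exp(-(z - 1)^2))
  expect_equal(peak_value(c2, c1), 50)
  expect_error(peak_value(c1, depth_dose_curve(z, rep(0, length(z)))), "zero")
})

test_that("literature interpolation is linear with exact endpoints", {
  expect_equal(interpolate_literature(0.31, 140, 0.48, 200, 155), 0.3525)
  expect_equal(interpolate_literature(0.31, 140, 0.48, 200, 140), 0.31)
  expect_equal(interpolate_literature(2, 100, 2, 200, 150), 2)
})
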