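test_that("pristine curve is peak-normalized on the 0.02 cm grid", {
  crv <- pristine_pdd(beam_spec(155))
  expect_equal(max(crv$dose), 1)
  expect_equal(crv$bin, 0.02, tolerance = 1e-12)
  expect_true(all(crv$dose >= 0))
  # peak sits just proximal of the nominal range
  pk <- crv$depths[which.max(crv$dose)]
  expect_lt(abs(pk - 15.6), 0.5)
})

test_that("near-zero range spread collapses the falloff to one bin", {
  s <- beam_spec(155, sigma_pristine = 0.01)
  expect_lte(compute_dfw(pristine_pdd(s)), 0.021)
})

test_that("calibration reproduces the measured pristine falloffs", {
  for (cfg in list(c(155, 0.24), c(200, 0.36))) {
    bs <- calibrated_beam(cfg[1])
    expect_equal(compute_dfw(pristine_pdd(bs)), cfg[2], tolerance = 0.011)
  }
})

test_that("calibration closes round trips, is monotone and idempotent", {
  base <- beam_spec(155)
  sig <- vapply(c(0.1, 0.24, 0.5, 1.0), function(target) {
    bs <- calibrate_sigma_to_dfw(base, target)
    expect_equal(compute_dfw(pristine_pdd(bs)), target, tolerance = 0.011)
    bs$sigma_pristine
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
  # near-linear: doubling the target roughly doubles sigma
  bs1 <- calibrate_sigma_to_dfw(base, 0.25)
  bs2 <- calibrate_sigma_to_dfw(base, 0.50)
  expect_equal(bs2$sigma_pristine / bs1$sigma_pristine, 2, tolerance = 0.05)
  # re-calibrating a calibrated spec is a fixed point
  bs3 <- calibrate_sigma_to_dfw(bs1, 0.25)
  expect_equal(bs3$sigma_pristine, bs1$sigma_pristine, tolerance = 0.02)
})

test_that("falloff width is invariant under range translation", {
  for (dR in c(-2, 0, 1.37)) {
    s <- beam_spec(155, range_water = 15.6 + dR, sigma_pristine = 2.0)
    expect_equal(compute_dfw(pristine_pdd(s)),
                 compute_dfw(pristine_pdd(beam_spec(155, sigma_pristine = 2.0))),
                 tolerance = 0.011)
  }
})

test_that("SOBP with one peak degenerates to the pristine curve", {
  bs <- calibrated_beam(155)
  expect_identical(build_sobp(bs, 3, n_peaks = 1L)$dose, pristine_pdd(bs)$dose)
})

test_that("30 mm SOBP plateau is flat within 2% and cannot sharpen the distal edge", {
  bs <- calibrated_beam(155)
  sob <- build_sobp(bs, 3, n_peaks = 13L)
  expect_lte(attr(sob, "flatness"), 0.02)
  expect_gte(compute_dfw(sob), compute_dfw(pristine_pdd(bs)) - 0.02)
  plateau <- sob$depths >= (15.6 - 3 + 0.15) & sob$depths <= (15.6 - 0.15)
  expect_lt(max(abs(sob$dose[plateau] - 1)), 0.03)
})
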