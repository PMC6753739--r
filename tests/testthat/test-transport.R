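test_that("a fully occupied phantom gives identical WEPL on every ray", {
  ph <- binomial_phantom(1, n = 20L)
  ph$occupancy[] <- 1
  w <- cast_rays(ph, margin_cm = 0)
  expect_equal(w$sigma_wepl, 0)
  expect_equal(unique(w$wepl_values), 20 * 0.04 * 1.11, tolerance = 1e-12)
})

test_that("per-column WEPL counts occupied voxels exactly", {
  ph <- binomial_phantom(0, n = 5L, spacing = 0.04)
  ph$occupancy[] <- 0
  ph$occupancy[2, 3, c(1, 3, 4)] <- 1  # one column with 3 resin voxels
  w <- cast_rays(ph, ray_spacing = 0.4, jitter_seed = 2, margin_cm = 0)
  wepl_air <- 5 * 0.04 * 0.0012
  wepl_col <- 3 * 0.04 * 1.11 + 2 * 0.04 * 0.0012
  expect_setequal(round(unique(w$wepl_values), 12),
                  round(c(wepl_air, wepl_col), 12))
})

test_that("WEPL variance of a binomial medium follows the closed form", {
  q <- 0.3; n <- 60L
  ph <- binomial_phantom(q, n = n, seed = 21L)
  w <- cast_rays(ph, ray_spacing = 0.4, jitter_seed = 4, margin_cm = 0)
  expect_gte(w$n_rays, 3000)
  z <- n * 0.04
  var_theory <- q * (1 - q) * z * 0.04 * (1.11 - 0.0012)^2  # cm^2
  expect_equal((w$sigma_wepl / 10)^2, var_theory, tolerance = 0.05)
})

test_that("zero-variance WEPL only translates the curve", {
  pr <- pristine_pdd(calibrated_beam(155))
  w <- gaussian_wepl(0.9, 0, n_rays = 100)
  w$wepl_values[] <- 0.9; w$sigma_wepl <- 0; w$mean_wepl <- 0.9
  deg <- degrade_curve(pr, w)
  expect_equal(compute_dfw(deg), compute_dfw(pr), tolerance = 0.0201)
  expect_equal(peak_value(deg, pr), 100, tolerance = 0.5)
  pk_shift <- pr$depths[which.max(pr$dose)] - deg$depths[which.max(deg$dose)]
  expect_equal(pk_shift, 0.9, tolerance = 0.0201)
})

test_that("Gaussian range mixing widens the falloff by quadrature in the curve's own shape constant", {
  bs <- calibrated_beam(155)
  pr <- pristine_pdd(bs)
  dfw_pr <- compute_dfw(pr)
  cshape <- 10 * dfw_pr / bs$sigma_pristine  # the family's DFW/sigma ratio
  sig_h <- 2.82
  deg <- degrade_curve(pr, gaussian_wepl(0.95, sig_h, n_rays = 4e4, seed = 8))
  want <- sqrt(dfw_pr^2 + (cshape * sig_h / 10)^2)
  expect_equal(compute_dfw(deg), want, tolerance = 0.02 / want)
  # quadrature closure: recover sigma_h from the widths within 10%
  got_sig <- sqrt(compute_dfw(deg)^2 - dfw_pr^2) * 10 / cshape
  expect_equal(got_sig, sig_h, tolerance = 0.10)
})

test_that("range mixing can only widen the falloff and lower the peak", {
  pr <- pristine_pdd(calibrated_beam(155))
  dfw_pr <- compute_dfw(pr)
  for (q in c(0.15, 0.4, 0.7)) {
    ph <- binomial_phantom(q, n = 40L, seed = round(100 * q))
    w <- cast_rays(ph, jitter_seed = 3, margin_cm = 0)
    deg <- degrade_curve(pr, w)
    expect_gte(compute_dfw(deg), dfw_pr - 1e-9)
    expect_lte(peak_value(deg, pr), 100 + 1e-9)
  }
})

test_that("a bulk-density slab shifts the curve without degrading it", {
  for (cfg in list(c(155, 0.24), c(200, 0.36))) {
    pr <- pristine_pdd(calibrated_beam(cfg[1]))
    slab <- simulate_slab(pr, 0.237, 4)
    expect_equal(compute_dfw(slab), compute_dfw(pr), tolerance = 0.0201)
    expect_equal(compute_dfw(slab), cfg[2], tolerance = 0.0201)
    expect_equal(peak_value(slab, pr), 100, tolerance = 0.5)
    pk_shift <- pr$depths[which.max(pr$dose)] -
      slab$depths[which.max(slab$dose)]
    expect_equal(pk_shift, 4 * 0.237, tolerance = 0.0201)
  }
  # zero thickness is the identity
  pr <- pristine_pdd(calibrated_beam(155))
  expect_equal(simulate_slab(pr, 0.237, 0)$dose, pr$dose, tolerance = 1e-12)
})
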