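test_that("kinetics hit their 25 degC references and scale with temperature", {
  k25 <- photosynthesis_kinetics(25, 0)
  expect_equal(k25$gammastar, pmodel_params()$gammastar25)
  expect_equal(k25$eta_star, 1)
  expect_equal(k25$patm, 101325)
  tg <- seq(0, 40, by = 1)
  gs <- photosynthesis_kinetics(tg, 0)$gammastar
  expect_true(all(diff(gs) > 0))
  # viscosity of water decreases with temperature
  expect_true(all(diff(photosynthesis_kinetics(tg, 0)$eta_star) < 0))
  # altitude lowers pressure and gammastar proportionally
  k2k <- photosynthesis_kinetics(25, 2000)
  expect_lt(k2k$patm, 101325)
  expect_equal(k2k$gammastar / k25$gammastar, k2k$patm / 101325)
  expect_error(photosynthesis_kinetics(75), "degC")
})

test_that("optimal chi respects its least-cost limits", {
  oc0 <- optimal_chi(20, 1e-12, 400)
  expect_equal(oc0$chi, 1, tolerance = 1e-5)
  vg <- seq(10, 5000, length.out = 60)
  chi <- optimal_chi(20, vg, 400)$chi
  expect_true(all(diff(chi) < 0))
  expect_true(all(chi > 0 & chi <= 1))
  # mj is the stated function of ci and gammastar, zero at ci = gammastar
  oc <- optimal_chi(20, 800, 400)
  k <- photosynthesis_kinetics(20, 0)
  expect_equal(oc$mj, (oc$ci - k$gammastar) / (oc$ci + 2 * k$gammastar))
  expect_error(optimal_chi(20, -5, 400), "nonnegative")
})

test_that("simulated LUE obeys its structural bounds and responses", {
  tg <- seq(0, 40, by = 0.25)
  lue_t <- pmodel_lue(tg, 800, 400)
  cf <- pmodel_params()$phi0_coeffs
  phi0 <- pmodel_params()$kphio * (cf[1] + cf[2] * tg + cf[3] * tg^2)
  expect_true(all(lue_t >= 0 & lue_t < phi0 + 1e-12))
  # interior temperature optimum on the [0, 40] grid
  am <- which.max(lue_t)
  expect_gt(am, 1); expect_lt(am, length(tg))
  # monotone non-increasing in VPD
  lue_v <- pmodel_lue(20, seq(50, 4000, length.out = 80), 400)
  expect_true(all(diff(lue_v) <= 1e-15))
  # no soil-moisture stress at saturation, monotone stress below theta*
  expect_equal(pmodel_lue(20, 800, 400, soil_m = 1),
               pmodel_lue(20, 800, 400, soil_m = 0.8))
  expect_lt(pmodel_lue(20, 800, 400, soil_m = 0.2),
            pmodel_lue(20, 800, 400, soil_m = 0.5))
  expect_error(pmodel_lue(20, 800, 400, soil_m = 0), "soil_m")
})

test_that("stylized experiments hold the other drivers at their medians", {
  comp <- small_composites()
  se <- stylized_experiment(comp, "vpd", n_grid = 40)
  expect_s3_class(se, "lue_response")
  expect_identical(nrow(se), 40L)
  expect_equal(range(se$x), range(comp$vpd))
  expect_true(all(diff(se$mu) <= 1e-15))
  # degenerate grid: constant driver gives a constant curve
  comp2 <- as.data.frame(comp); comp2$vpd <- 750
  se2 <- stylized_experiment(comp2, "vpd", n_grid = 10)
  expect_true(all(se2$mu == se2$mu[1]))
  # no diffuse-radiation pathway: the cloudiness curve is exactly flat
  se_ci <- stylized_experiment(comp, "ci", n_grid = 10)
  expect_true(all(se_ci$mu == se_ci$mu[1]))
  expect_error(stylized_experiment(comp, "fapar"), "one of")
})
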