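test_that("identical seeds give identical networks, different seeds differ", {
  a <- generate_site_network(synth_config(n_sites = 3, seed = 123))
  b <- generate_site_network(synth_config(n_sites = 3, seed = 123))
  expect_identical(a, b)
  d <- generate_site_network(synth_config(n_sites = 3, seed = 124))
  expect_false(identical(a$daily$gpp, d$daily$gpp))
})

test_that("generated records satisfy their physical invariants", {
  net <- small_network()
  d <- net$daily
  expect_true(all(d$sw_in <= d$sw_in_pot + 1e-9))
  expect_true(all(d$sw_in_pot >= 0))
  expect_true(all(d$vpd_day >= 0))
  expect_true(all(d$soil_m > 0 & d$soil_m <= 1))
  expect_true(all(d$gapfill_frac >= 0 & d$gapfill_frac <= 1))
  expect_true(all(net$truth$lue_true > 0))
  obs <- d$fapar_obs[is.finite(d$fapar_obs)]
  expect_true(all(obs > 0 & obs <= 1))
  dif <- d$ppfd_dif[is.finite(d$ppfd_dif)]
  expect_true(all(dif >= 0))
  # diffuse flux never exceeds the total potential photon flux
  expect_true(all(dif <= d$sw_in_pot[is.finite(d$ppfd_dif)] * 2.04 + 1e-9))
})

test_that("noise-free generation closes the LUE identity exactly", {
  cfg <- synth_config(n_sites = 2, years_per_site = 2, gamma_shape = Inf,
                      lue_process_sd = 0, seed = 7)
  net <- generate_site_network(cfg)
  d <- net$daily; tr <- net$truth
  ppfd <- d$sw_in * 2.04e-6 * 86400
  ok <- ppfd > 1e-6
  lue_back <- (d$gpp[ok] / 12.011) / (ppfd[ok] * tr$fapar_true[ok])
  expect_lt(max(abs(lue_back - tr$lue_true[ok]) / tr$lue_true[ok]), 1e-10)
})

test_that("drawn site intercepts have the configured variance", {
  cfg <- synth_config(n_sites = 50, years_per_site = 1, seed = 31)
  net <- generate_site_network(cfg)
  a <- tapply(net$truth$site_intercept, net$truth$site_id, unique)
  v <- var(as.numeric(a))
  # sampling sd of a variance estimate: sigma^2 * sqrt(2/(n-1))
  expect_lt(abs(v - cfg$sd_site^2),
            2 * cfg$sd_site^2 * sqrt(2 / (50 - 1)))
})

test_that("configuration invariants are validated", {
  expect_error(synth_config(n_sites = 0))
  expect_error(synth_config(gamma_shape = 0))
  expect_error(synth_config(gap_rate = 1))
  expect_error(synth_config(sd_site = -0.1))
  expect_error(synth_config(true_coefficients = c(intercept = -1)),
               "true_coefficients")
})

test_that("sparse fAPAR sampling matches the configured interval", {
  cfg <- synth_config(n_sites = 1, years_per_site = 1,
                      fapar_obs_interval_days = 8, seed = 3)
  net <- generate_site_network(cfg)
  idx <- which(is.finite(net$daily$fapar_obs))
  expect_true(all(diff(idx) == 8))
})
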