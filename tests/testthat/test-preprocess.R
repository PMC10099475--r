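test_that("shortwave-to-photon-flux conversion uses 2.04 umol/J", {
  expect_identical(ppfd_from_shortwave(0), 0)
  expect_equal(ppfd_from_shortwave(200), 200 * 2.04e-6 * 86400)
  expect_equal(ppfd_from_shortwave(200), 35.2512)
  expect_error(ppfd_from_shortwave(-1), "nonnegative")
})

test_that("cloudiness index endpoints and arithmetic", {
  expect_equal(cloudiness_index(400, 400), 0)
  expect_equal(cloudiness_index(0, 400), 1)
  expect_equal(cloudiness_index(300, 400), 0.25)
  expect_true(is.na(cloudiness_index(10, 0)))
})

test_that("diffuse transmittance follows the Bristow form", {
  # forced zero at T_T = B, all-diffuse limit as T_T -> 0
  expect_equal(diffuse_transmittance(0.889, 0.889), 0)
  tt <- 1e-8
  expect_equal(diffuse_transmittance(tt, 0.889) / tt, 1)
  # hand evaluation: exponent 0.6*(1 - 0.889/0.5)/0.489 = -0.95460,
  # exp = 0.38496, T_d = 0.5*(1 - 0.38496) = 0.30752
  expect_equal(diffuse_transmittance(0.5, 0.889),
               0.5 * (1 - exp(0.6 * (1 - 0.889 / 0.5) / (0.889 - 0.4))))
  expect_equal(diffuse_transmittance(0.5, 0.889), 0.3075, tolerance = 1e-3)
  # bounded by the total transmittance
  tt <- seq(0.01, 1, by = 0.01)
  td <- diffuse_transmittance(tt, 0.889)
  expect_true(all(td >= 0 & td <= tt))
  expect_error(diffuse_transmittance(0, 0.889), "positive")
  expect_error(diffuse_transmittance(0.5, 0.4), "B must be")
})

test_that("Bristow coefficient is recovered from exact data", {
  set.seed(11)
  tt <- runif(200, 0.05, 1)
  td <- diffuse_transmittance(tt, 0.75)
  expect_equal(fit_bristow(td, tt)$B, 0.75, tolerance = 1e-6)
  expect_error(fit_bristow(td[1:5], tt[1:5]), "at least 10")
})

test_that("diffuse gap-filling never overwrites observations", {
  set.seed(2)
  rec <- data.frame(sw_in = c(200, 300, 0.889 * 350),
                    sw_in_pot = c(400, 400, 350),
                    ppfd_dif = c(150, NA, NA))
  out <- gapfill_diffuse(rec, B = 0.889)
  expect_identical(out$ppfd_dif[1], 150)
  expect_false(is.na(out$ppfd_dif[2]))
  # at T_T = B the filled diffuse flux is zero
  expect_equal(out$ppfd_dif[3], 0)
  expect_identical(out$ppfd_dif_filled, c(FALSE, TRUE, TRUE))
  # all-missing table: every value filled within physical bounds
  rec2 <- data.frame(sw_in = runif(50, 10, 300), sw_in_pot = 320,
                     ppfd_dif = NA_real_)
  out2 <- gapfill_diffuse(rec2, 0.889)
  expect_true(all(is.finite(out2$ppfd_dif)))
  expect_true(all(out2$ppfd_dif >= 0 &
                    out2$ppfd_dif <= out2$sw_in * 2.04 + 1e-9))
})

test_that("fAPAR interpolation filters saturated values and outliers", {
  d <- seq(as.Date("2001-01-01"), by = 4, length.out = 30)
  vals <- rep(0.6, 30); vals[10] <- 1.0
  out <- interpolate_fapar(d, vals, d)
  expect_equal(out, rep(0.6, 30))
  # an outlier far beyond 3 IQR is discarded before fitting
  set.seed(4)
  vals2 <- 0.6 + rnorm(30, 0, 0.01); vals2[5] <- 0.05
  out2 <- interpolate_fapar(d, vals2, d)
  expect_true(all(abs(out2 - 0.6) < 0.05))
  expect_error(interpolate_fapar(d[1:3], rep(0.5, 3), d), "4 retained")
})

test_that("fAPAR interpolation reconstructs a smooth seasonal course", {
  days <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  truth <- 0.5 + 0.3 * sin(2 * pi * seq_along(days) / 365)
  obs_idx <- seq(1, length(days), by = 4)
  rec <- interpolate_fapar(days[obs_idx], truth[obs_idx], days)
  expect_lt(max(abs(rec - truth)), 0.02)
})

test_that("site-day filters drop exactly the offending records", {
  th <- filter_thresholds()
  base <- data.frame(gpp = 5, gapfill_frac = 0.1, ppfd = 30, fapar = 0.5)
  rec <- base[rep(1, 10), ]
  rec$gapfill_frac[2] <- 0.6     # too much gap-filling
  rec$gpp[5] <- -0.3             # negative GPP
  rec$fapar[8] <- 0.001          # near-zero absorbed light...
  rec$gpp[8] <- 1e-4             # ...while apparent LUE stays feasible
  out <- filter_site_days(rec, th)
  expect_identical(nrow(out$records), 7L)
  expect_identical(unname(out$audit[c("gapfill", "negative_gpp",
                                      "low_absorbed_light", "lue_cap")]),
                   c(1L, 1L, 1L, 0L))
  # a record gap-filled at exactly one half is dropped (strict rule)
  rec2 <- base; rec2$gapfill_frac <- 0.5
  expect_identical(nrow(filter_site_days(rec2, th)$records), 0L)
  # infeasible apparent LUE is dropped
  rec3 <- base; rec3$gpp <- 0.13 * 12.011 * 30 * 0.5
  expect_identical(unname(filter_site_days(rec3, th)$audit[["lue_cap"]]), 1L)
})

test_that("growing-season mask applies the scaled-quantile rule", {
  gpp <- 0:99
  q <- quantile(gpp, c(0.05, 0.95), names = FALSE)  # 4.95, 94.05
  thr <- q[1] + 0.2 * (q[2] - q[1])
  m <- growing_season_mask(gpp)
  expect_identical(m, gpp > thr)
  expect_identical(sum(m), sum(0:99 >= 23))
  expect_error(growing_season_mask(rep(3, 50)), "degenerate")
  # monotone series: the mask is a suffix
  set.seed(1)
  x <- cumsum(runif(60))
  m2 <- growing_season_mask(x)
  expect_identical(m2, seq_along(x) > max(which(!m2)))
})

test_that("window compositing follows the 15-day accumulation rule", {
  days <- seq(as.Date("2002-06-01"), by = "day", length.out = 15)
  rec <- data.frame(site_id = "A", date = days, gpp = 6, ppfd = 30,
                    fapar = 0.5, sw_in = 200, sw_in_pot = 400,
                    ta_day = 20, vpd_day = 800, soil_m = 0.8)
  comp <- compose_windows(rec)
  expect_identical(nrow(comp), 1L)
  expect_equal(comp$lue, (15 * 6 / 12.011) / (15 * 30 * 0.5))
  expect_equal(comp$lue, 0.0333, tolerance = 1e-3)
  # constant forcing: window means equal the daily values
  expect_equal(comp$temp, 20)
  expect_equal(comp$ci, 0.5)
  expect_identical(comp$year, 2002L)
  # a 44-day run yields 2 windows and discards the 14-day stub
  rec44 <- rec[rep(1, 44), ]; rec44$date <- days[1] + 0:43
  expect_identical(nrow(compose_windows(rec44)), 2L)
})

test_that("total windows equal the sum of floor(run length / 15)", {
  set.seed(8)
  days <- seq(as.Date("2002-01-01"), by = "day", length.out = 400)
  keep <- runif(400) < 0.9
  rec <- data.frame(site_id = "A", date = days[keep], gpp = 5, ppfd = 30,
                    fapar = 0.5, sw_in = 200, sw_in_pot = 400,
                    ta_day = 15, vpd_day = 700, soil_m = 0.9)
  runs <- rle(cumsum(!keep)[keep])$lengths
  comp <- compose_windows(rec)
  expect_identical(nrow(comp), as.integer(sum(runs %/% 15)))
  expect_true(all(comp$n_days == 15))
  memb <- attr(comp, "membership")
  expect_identical(nrow(memb), 15L * nrow(comp))
})

test_that("the pipeline reproduces truth LUE exactly on noise-free data", {
  cfg <- synth_config(n_sites = 2, years_per_site = 2, gamma_shape = Inf,
                      lue_process_sd = 0, fapar_noise_sd = 0,
                      fapar_outlier_rate = 0, fapar_unity_rate = 0,
                      gap_rate = 0, seed = 5)
  net <- generate_site_network(cfg)
  daily <- net$daily
  daily$fapar_obs <- net$truth$fapar_true  # dense, exact fAPAR
  comp <- make_composites(daily, filter_thresholds(fapar_source = "column"),
                          gs_flags = net$truth)
  expect_gt(nrow(comp), 10)
  # oracle: absorbed-light-weighted truth aggregated over the same days
  memb <- attr(comp, "membership")
  dkey <- paste(daily$site_id, daily$date)
  i <- match(paste(memb$site_id, memb$date), dkey)
  ppfd <- daily$sw_in[i] * 2.04e-6 * 86400
  tr <- net$truth[match(paste(memb$site_id, memb$date),
                        paste(net$truth$site_id, net$truth$date)), ]
  wkey <- paste(memb$site_id, memb$window_index)
  expected <- tapply(tr$lue_true * tr$fapar_true * ppfd, wkey, sum) /
    (tapply(ppfd, wkey, sum) * tapply(tr$fapar_true, wkey, mean))
  got <- comp$lue[match(names(expected),
                        paste(comp$site_id, comp$window_index))]
  expect_lt(max(abs(got - expected) / expected), 1e-10)
})

test_that("make_composites audits exclusions and fits Bristow en route", {
  comp <- small_composites()
  audit <- attr(comp, "audit")
  expect_true(all(c("gapfill", "negative_gpp", "low_absorbed_light",
                    "lue_cap", "non_growing_season", "windows")
                  %in% names(audit)))
  expect_equal(unname(audit[["windows"]]), nrow(comp))
  br <- attr(comp, "bristow")
  expect_s3_class(br, "bristow_fit")
  # generator writes diffuse radiation with B = 0.889 and no noise
  expect_equal(br$B, 0.889, tolerance = 1e-4)
  expect_true(all(comp$ci > 0 & comp$ci < 1))
  expect_true(all(comp$fapar > 0 & comp$fapar <= 1))
  expect_true(all(comp$lue > 0))
})
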