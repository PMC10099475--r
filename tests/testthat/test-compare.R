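test_that("Beer-Lambert fAPAR from LAI", {
  expect_identical(fapar_from_lai(0), 0)
  expect_equal(fapar_from_lai(2, 0.5), 1 - exp(-1))
  lai <- seq(0, 12, by = 0.5)
  f <- fapar_from_lai(lai)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))
  expect_gt(fapar_from_lai(40), 1 - 1e-8)
  expect_error(fapar_from_lai(-1), "nonnegative")
  expect_error(fapar_from_lai(2, 0), "positive")
})

test_that("Nash-Sutcliffe efficiency identities", {
  o <- c(1, 2, 3)
  expect_equal(nash_sutcliffe(o, o), 1)
  expect_equal(nash_sutcliffe(o, rep(mean(o), 3)), 0)
  expect_equal(nash_sutcliffe(o, c(1, 2, 4)), 0.5)
  # invariance under a common affine transform
  set.seed(3)
  obs <- rnorm(40); sim <- obs + rnorm(40, 0, 0.5)
  expect_equal(nash_sutcliffe(obs, sim),
               nash_sutcliffe(3 * obs - 7, 3 * sim - 7))
  expect_error(nash_sutcliffe(o, c(1, 2)), "equal length")
  expect_error(nash_sutcliffe(rep(1, 5), rnorm(5)), "constant")
})

test_that("the common design applied to model output reuses the data windows", {
  cfg <- synth_config(n_sites = 4, years_per_site = 2, seed = 21)
  net <- generate_site_network(cfg)
  daily <- net$daily
  daily$fapar_obs <- net$truth$fapar_true
  th <- filter_thresholds(fapar_source = "column")
  comp <- suppressWarnings(make_composites(daily, th))
  mo <- rbind(
    data.frame(model = "clone", site_id = daily$site_id, date = daily$date,
               gpp_sim = daily$gpp, fapar_sim = net$truth$fapar_true),
    data.frame(model = "double", site_id = daily$site_id, date = daily$date,
               gpp_sim = 2 * daily$gpp, fapar_sim = net$truth$fapar_true))
  mc <- model_lue_composites(mo, daily, th, composites = comp)
  expect_identical(sort(names(mc)), c("clone", "double"))
  # a model identical to the data reproduces the data composites
  m1 <- mc$clone
  i <- match(paste(m1$site_id, m1$window_index),
             paste(comp$site_id, comp$window_index))
  expect_equal(m1$lue, comp$lue[i], tolerance = 1e-12)
  # doubling GPP doubles LUE exactly...
  expect_equal(mc$double$lue, 2 * mc$clone$lue, tolerance = 1e-12)
  # ...which in a log-link gamma fit shifts only the intercept, by log 2
  f1 <- lue_glmm(mc$clone, lue_design(random = "none"))
  f2 <- lue_glmm(mc$double, lue_design(random = "none"))
  expect_equal(unname(f2$beta[1] - f1$beta[1]), log(2), tolerance = 1e-8)
  expect_equal(f1$beta[-1], f2$beta[-1], tolerance = 1e-8)
})

test_that("saturating LAI drives fAPAR to one and LUE to GPP/PPFD", {
  cfg <- synth_config(n_sites = 2, years_per_site = 2, seed = 22)
  net <- generate_site_network(cfg)
  daily <- net$daily
  daily$fapar_obs <- net$truth$fapar_true
  th <- filter_thresholds(fapar_source = "column")
  comp <- suppressWarnings(make_composites(daily, th))
  mo <- data.frame(model = "dense", site_id = daily$site_id,
                   date = daily$date, gpp_sim = daily$gpp, lai_sim = 1e6)
  mc <- model_lue_composites(mo, daily, th, composites = comp)
  m <- mc$dense
  expect_true(all(abs(m$fapar - 1) < 1e-12))
  i <- match(paste(m$site_id, m$window_index),
             paste(comp$site_id, comp$window_index))
  expect_equal(m$lue, comp$lue[i] * comp$fapar[i], tolerance = 1e-12)
})

test_that("ensemble fitting isolates per-model failures", {
  comp <- small_composites()
  good <- as.data.frame(comp)
  bad <- good; bad$lue <- -abs(bad$lue)   # unusable response
  ens <- suppressWarnings(
    ensemble_fit(list(ok = comp, broken = bad),
                 lue_design(random = "site_only"),
                 variables = c("temp", "vpd")))
  expect_identical(length(ens), 2L)
  expect_false(is.null(ens$ok$fit))
  expect_identical(sort(names(ens$ok$curves)), c("temp", "vpd"))
  expect_null(ens$broken$fit)
  expect_false(ens$broken$converged)
  expect_true(nzchar(ens$broken$error))
  expect_error(ensemble_fit(list()), "empty")
})
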