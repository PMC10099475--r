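test_that("build_design emits the preferred six-column fixed matrix", {
  comp <- small_composites()
  bd <- build_design(comp, lue_design())
  expect_identical(colnames(bd$X),
                   c("(Intercept)", "temp_c", "temp_c2", "lvpd", "lsm",
                     "lci"))
  # default centring: the linear temperature column has mean zero
  expect_lt(abs(mean(bd$X[, "temp_c"])), 1e-12)
  bd0 <- build_design(comp, lue_design(character(0)))
  expect_identical(colnames(bd0$X), "(Intercept)")
  expect_true(all(bd0$X == 1))
})

test_that("records violating a log transform are dropped with a count", {
  comp <- as.data.frame(small_composites())
  comp$soil_m[3] <- 0
  comp$vpd[7] <- NA
  bd <- build_design(comp, lue_design())
  expect_identical(bd$n_dropped, 2L)
  expect_identical(nrow(bd$frame), nrow(comp) - 2L)
})

test_that("intercept-only gamma GLM MLE equals the sample mean", {
  set.seed(10)
  y <- rgamma(200, shape = 8, rate = 8 / 0.02)
  d <- data.frame(lue = y, site_id = "A", year = 2001)
  fit <- lue_glmm(d, lue_design(character(0), random = "none"))
  expect_equal(unname(exp(fit$beta[1])), mean(y), tolerance = 1e-10)
  # the jointly profiled gamma shape is close to the generating one
  expect_gt(fit$shape, 5); expect_lt(fit$shape, 12)
})

test_that("Laplace marginal likelihood matches Gauss-Hermite quadrature", {
  set.seed(42)
  n_site <- 3; n_obs <- 8
  site <- factor(rep(1:n_site, each = n_obs))
  x1 <- rnorm(n_site * n_obs)
  u <- rnorm(n_site, 0, 0.3)
  shape <- 30
  mu <- exp(-1 + 0.4 * x1 + u[as.integer(site)])
  y <- rgamma(length(mu), shape, rate = shape / mu)
  d <- data.frame(lue = y, vpd = exp(x1), site_id = site, year = 1)
  fit <- lue_glmm(d, lue_design("log_vpd", random = "site_only"))
  ll_oracle <- agq_loglik(y, cbind(1, x1), site, fit$beta,
                          sqrt(fit$sigma2_site), fit$shape)
  expect_lt(abs(fit$loglik - ll_oracle), 1e-3)
})

test_that("information criteria identities hold exactly", {
  fit <- small_fit()
  expect_identical(fit$aic, -2 * fit$loglik + 2 * fit$df)
  expect_identical(fit$bic, -2 * fit$loglik + fit$df * log(fit$n))
  ll <- logLik(fit)
  expect_equal(AIC(fit$fit), fit$aic)
  expect_identical(attr(ll, "df"), fit$df)
})

test_that("fixed-only predictions shrink toward the population mean", {
  fit <- small_fit()
  bl <- fit$blups$site_id
  s_pos <- rownames(bl)[which.max(bl[, 1])]
  expect_gt(bl[s_pos, 1], 0)
  nd <- fit$frame[fit$frame$site_id == s_pos, ]
  nd$site_id <- s_pos
  nd$year <- as.character(nd$year_f)
  p_fix <- predict(fit, nd, include_random = FALSE)
  p_full <- predict(fit, nd, include_random = TRUE)
  expect_true(all(p_fix < p_full))
  # fixed-only predictions have smaller spread than full predictions
  v_fix <- var(predict(fit, include_random = FALSE))
  v_full <- var(predict(fit, include_random = TRUE))
  expect_lt(v_fix, v_full)
  # unknown site falls back to the fixed-effects prediction
  nd2 <- nd[1, ]; nd2$site_id <- "NOSUCH"; nd2$year <- "1900"
  expect_equal(predict(fit, nd2, include_random = TRUE),
               predict(fit, nd2, include_random = FALSE))
})

test_that("conditional responses are median-consistent and sign-correct", {
  fit <- small_fit()
  rc <- conditional_response(fit, "vpd", n_grid = 101)
  expect_true(all(rc$mu > 0))
  # beta3 < 0: the VPD curve decreases monotonically
  expect_lt(fit$beta[["lvpd"]], 0)
  expect_true(all(diff(rc$mu) < 0))
  # the curve at the variable's own median equals the all-median prediction
  md <- as.data.frame(as.list(fit$medians))
  mu_med <- predict(fit, md)
  rc_at_med <- conditional_response(fit, "vpd", n_grid = 3)
  nd <- md; nd$vpd <- rc_at_med$x[2]
  expect_equal(rc_at_med$mu[2], unname(predict(fit, nd)))
  expect_error(conditional_response(fit, "ppfd"), "not part")
  pres <- attr(rc, "partial_residuals")
  expect_identical(nrow(pres), fit$n)
})

test_that("temperature optimum is the vertex of the fitted quadratic", {
  fake <- structure(list(beta = c(temp_c = 2, temp_c2 = -0.05),
                         design = lue_design(), temp_center = 0),
                    class = "lue_glmm")
  expect_equal(temperature_optimum(fake), 20)
  fake$temp_center <- 10
  expect_equal(temperature_optimum(fake), 30)
  fake$beta["temp_c2"] <- 0.01
  out <- temperature_optimum(fake)
  expect_identical(unclass(out)[1], Inf)
  expect_true(attr(out, "flagged"))
  fake$design <- lue_design("temp_linear")
  expect_error(temperature_optimum(fake), "quadratic")
})

test_that("variance partition normalises to one and needs nesting", {
  fit <- small_fit()
  vp <- variance_partition(fit)
  expect_identical(names(vp), c("site", "year_in_site", "residual"))
  expect_equal(sum(vp), 1, tolerance = 1e-12)
  expect_true(all(vp >= 0))
  fit_site <- suppressWarnings(
    lue_glmm(small_composites(), lue_design(random = "site_only")))
  expect_error(variance_partition(fit_site), "year_in_site")
})

test_that("the selection ladder ranks designs on one observation set", {
  comp <- small_composites()
  two <- list(A = lue_design(label = "A"), B = lue_design(label = "B"))
  tab <- suppressWarnings(selection_ladder(comp, two))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$aic[1], tab$aic[2])
  expect_equal(tab$loglik[1], tab$loglik[2])
  lad <- default_ladder()
  expect_identical(names(lad), sprintf("M%02d", 1:8))
  expect_identical(lad$M06$fixed,
                   c("temp_poly2", "log_vpd", "log_soil_m", "log_ci"))
})

test_that("simulate and residuals behave like the model family", {
  fit <- small_fit()
  s <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(s), c(fit$n, 2L))
  expect_true(all(s > 0))
  r <- residuals(fit, type = "working")
  expect_equal(r, (fit$frame$lue - fitted(fit)) / fitted(fit))
  expect_identical(length(residuals(fit, "deviance")), fit$n)
})

test_that("leave-one-site-out CV approaches 1 in the perfect-model limit", {
  cfg <- synth_config(n_sites = 8, years_per_site = 2, sd_site = 0,
                      sd_year = 0, gamma_shape = Inf, lue_process_sd = 0,
                      fapar_noise_sd = 0, fapar_outlier_rate = 0,
                      fapar_unity_rate = 0, seed = 9)
  net <- generate_site_network(cfg)
  daily <- net$daily
  daily$fapar_obs <- net$truth$fapar_true
  comp <- make_composites(daily, filter_thresholds(fapar_source = "column"),
                          gs_flags = net$truth)
  cv <- loo_site_cv(comp, lue_design())
  expect_gt(cv$r2_cv, 0.99)
  expect_gt(cv$r2_fixed, 0.99)
  expect_identical(length(cv$skipped), 0L)
  expect_error(loo_site_cv(comp[comp$site_id == comp$site_id[1], ]),
               "3 sites")
})
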