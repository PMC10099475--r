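# shared fixtures and independent oracles for the test suite

# memoised small synthetic network + composites + fit, reused across files
.fixture_env <- new.env(parent = emptyenv())

small_network <- function() {
  if (is.null(.fixture_env$net))
    .fixture_env$net <- generate_site_network(
      synth_config(n_sites = 8, years_per_site = 3, seed = 42))
  .fixture_env$net
}

small_composites <- function() {
  if (is.null(.fixture_env$comp)) {
    net <- small_network()
    .fixture_env$comp <- suppressWarnings(
      make_composites(net$daily, gs_flags = net$truth))
  }
  .fixture_env$comp
}

small_fit <- function() {
  if (is.null(.fixture_env$fit))
    .fixture_env$fit <- suppressWarnings(
      lue_glmm(small_composites(), lue_design(), temp_center = 15))
  .fixture_env$fit
}

# composites via the full pipeline but with the generator's noise-free
# growing-season truth, the conditions used in the recovery studies
truth_mask_composites <- function(net, thresholds = filter_thresholds()) {
  suppressWarnings(make_composites(net$daily, thresholds,
                                   gs_flags = net$truth))
}

# independent oracle: marginal log-likelihood of a gamma GLMM with site
# random intercepts by adaptive Gauss-Hermite quadrature (one 1-D
# integral per site, mode-centred and curvature-scaled nodes)
agq_loglik <- function(y, X, site, beta, sigma, shape, nodes = 15) {
  gh <- pracma::gaussHermite(nodes)
  eta0 <- as.numeric(X %*% beta)
  total <- 0
  for (s in unique(site)) {
    i <- site == s
    f <- function(u) sum(stats::dgamma(y[i], shape = shape,
                                       rate = shape / exp(eta0[i] + u),
                                       log = TRUE)) +
      stats::dnorm(u, 0, sigma, log = TRUE)
    uhat <- stats::optimize(function(u) -f(u), c(-6 * sigma, 6 * sigma),
                            tol = 1e-12)$minimum
    h <- 1e-4
    d2 <- -(f(uhat + h) - 2 * f(uhat) + f(uhat - h)) / h^2
    sc <- sqrt(2 / d2)
    lg <- vapply(gh$x, function(x) f(uhat + sc * x) + x^2, numeric(1))
    m <- max(lg)
    total <- total + log(sc * sum(gh$w * exp(lg - m))) + m
  }
  total
}

# independent oracle for daily-mean potential radiation: numerical
# integration of the cosine of the solar zenith angle at 1-minute steps
potential_radiation_numeric <- function(latitude, day_of_year) {
  phi <- latitude * pi / 180
  g <- 2 * pi * day_of_year / 365
  dr <- 1 + 0.033 * cos(g)
  delta <- 0.409 * sin(g - 1.39)
  tmin <- seq(0, 24, by = 1 / 60)[-1]
  hour_angle <- (tmin - 12) * pi / 12
  cosz <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(hour_angle)
  mean(1361 * dr * pmax(cosz, 0))
}
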