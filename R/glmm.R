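# fixed-effect term registry: composite columns consumed, model columns
# emitted, and whether a log transform restricts the support
.term_registry <- list(
  temp_poly2    = list(raw = "temp",   cols = c("temp_c", "temp_c2")),
  temp_linear   = list(raw = "temp",   cols = "temp_c"),
  log_vpd       = list(raw = "vpd",    cols = "lvpd",  log_of = "vpd"),
  vpd_linear    = list(raw = "vpd",    cols = "vpd"),
  log_soil_m    = list(raw = "soil_m", cols = "lsm",   log_of = "soil_m"),
  soil_m_linear = list(raw = "soil_m", cols = "soil_m"),
  log_ci        = list(raw = "ci",     cols = "lci",   log_of = "ci"),
  ci_linear     = list(raw = "ci",     cols = "ci"),
  elevation     = list(raw = "elevation", cols = "elevation"),
  co2           = list(raw = "co2",    cols = "co2"),
  ci_x_fapar    = list(raw = c("ci", "fapar"), cols = "ci_fapar"),
  td_x_fapar    = list(raw = c("td", "fapar"), cols = "td_fapar"),
  ppfd          = list(raw = "ppfd",   cols = "ppfd"))

#' Declare a LUE model design
#'
#' A declarative description of the fixed and random structure of a
#' gamma LUE model.  Fixed terms are drawn from a fixed vocabulary:
#' `temp_poly2` (centred quadratic in temperature), `temp_linear`,
#' `log_vpd`, `vpd_linear`, `log_soil_m`, `soil_m_linear`, `log_ci`,
#' `ci_linear`, `elevation`, `co2`, `ci_x_fapar` and `td_x_fapar`
#' (products of cloudiness index or diffuse transmittance with fAPAR),
#' and `ppfd`.  The family is always gamma with a log link.
#'
#' @param fixed Character vector of fixed term names (may be empty for
#'   an intercept-only model).
#' @param random One of `"year_in_site"` (site intercepts plus
#'   year-within-site intercepts), `"site_only"`, `"year_only"`,
#'   `"none"`.
#' @param label Optional short label used in selection tables.
#' @return An object of class `lue_design`.
#' @examples
#' lue_design()   # the preferred design: quadratic temperature,
#'                # log VPD, log soil moisture, log cloudiness
#' @export
lue_design <- function(fixed = c("temp_poly2", "log_vpd", "log_soil_m",
                                 "log_ci"),
                       random = c("year_in_site", "site_only",
                                  "year_only", "none"),
                       label = NULL) {
  random <- match.arg(random)
  fixed <- as.character(fixed)
  if (anyDuplicated(fixed)) stop("fixed terms must be unique")
  unknown <- setdiff(fixed, names(.term_registry))
  if (length(unknown))
    stop("unknown fixed term(s): ", paste(unknown, collapse = ", "))
  structure(list(fixed = fixed, random = random,
                 label = label %||%
                   if (length(fixed)) paste(fixed, collapse = " + ")
                   else "intercept-only"),
            class = "lue_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lue_design <- function(x, ...) {
  cat(sprintf("LUE model design '%s'\n  fixed:  ~ %s\n  random: %s\n",
              x$label,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$random))
  invisible(x)
}

#' The backward model-selection ladder of candidate designs
#'
#' Eight nested-to-simpler candidate designs, from a maximal model with
#' elevation, CO2 and a cloudiness-by-fAPAR interaction down to an
#' untransformed linear model, all sharing year-within-site random
#' intercepts.  The log-cloudiness design (M06 analogue) is the
#' preferred structure pursued in the analysis.
#'
#' @return A named list of [lue_design()] objects.
#' @export
default_ladder <- function() {
  list(
    M01 = lue_design(c("temp_poly2", "log_vpd", "log_soil_m", "elevation",
                       "co2", "ci_x_fapar"), label = "M01"),
    M02 = lue_design(c("temp_poly2", "log_vpd", "log_soil_m", "elevation",
                       "ci_x_fapar"), label = "M02"),
    M03 = lue_design(c("temp_poly2", "log_vpd", "log_soil_m",
                       "ci_x_fapar"), label = "M03"),
    M04 = lue_design(c("temp_poly2", "log_vpd", "log_soil_m"),
                     label = "M04"),
    M05 = lue_design(c("temp_poly2", "log_vpd", "log_soil_m",
                       "td_x_fapar"), label = "M05"),
    M06 = lue_design(c("temp_poly2", "log_vpd", "log_soil_m", "log_ci"),
                     label = "M06"),
    M07 = lue_design(c("temp_poly2", "log_vpd", "log_ci"), label = "M07"),
    M08 = lue_design(c("temp_linear", "vpd_linear", "soil_m_linear",
                       "ci_linear"), label = "M08"))
}

# transformed model frame for a set of designs; rows must be complete
# and positive under every log transform used by any design
.build_frame <- function(composites, designs, temp_center = NULL) {
  if (inherits(designs, "lue_design")) designs <- list(designs)
  terms <- unique(unlist(lapply(designs, `[[`, "fixed")))
  reg <- .term_registry[terms]
  raw <- unique(c("lue", unlist(lapply(reg, `[[`, "raw"))))
  miss <- setdiff(raw, names(composites))
  if (length(miss))
    stop("composites lack column(s): ", paste(miss, collapse = ", "))
  logged <- unique(unlist(lapply(reg, `[[`, "log_of")))

  ok <- rep(TRUE, nrow(composites))
  for (v in raw) ok <- ok & is.finite(composites[[v]])
  ok <- ok & composites$lue > 0
  for (v in logged) ok <- ok & composites[[v]] > 0
  d <- composites[ok, , drop = FALSE]
  if (nrow(d) == 0) stop("no usable rows after dropping incomplete records")

  if (is.null(temp_center))
    temp_center <- if ("temp" %in% names(d)) mean(d$temp) else 0
  fr <- data.frame(lue = d$lue)
  if ("temp" %in% names(d)) {
    fr$temp <- d$temp
    fr$temp_c <- d$temp - temp_center
    fr$temp_c2 <- fr$temp_c^2
  }
  for (v in c("vpd", "soil_m", "ci", "td", "fapar", "co2", "elevation",
              "ppfd"))
    if (v %in% names(d)) fr[[v]] <- d[[v]]
  if (!is.null(fr$vpd)) fr$lvpd <- log(fr$vpd)
  if (!is.null(fr$soil_m)) fr$lsm <- log(fr$soil_m)
  if (!is.null(fr$ci)) fr$lci <- log(pmax(fr$ci, .Machine$double.eps))
  if (!is.null(fr$ci) && !is.null(fr$fapar)) fr$ci_fapar <- fr$ci * fr$fapar
  if (!is.null(fr$td) && !is.null(fr$fapar)) fr$td_fapar <- fr$td * fr$fapar
  fr$site_id <- factor(d$site_id)
  fr$year_f <- factor(d$year)
  fr$site_year <- factor(paste(d$site_id, d$year, sep = ":"))
  attr(fr, "temp_center") <- temp_center
  attr(fr, "n_dropped") <- sum(!ok)
  attr(fr, "rows") <- which(ok)
  fr
}

.fixed_formula_rhs <- function(design) {
  cols <- unlist(lapply(.term_registry[design$fixed], `[[`, "cols"))
  if (length(cols)) paste(cols, collapse = " + ") else "1"
}

.random_formula_rhs <- function(design) {
  switch(design$random,
         year_in_site = "(1 | site_id) + (1 | site_year)",
         site_only = "(1 | site_id)",
         year_only = "(1 | year_f)",
         none = NULL)
}

#' Build the response, design matrix and grouping structure
#'
#' Lower-level access to the model frame construction used by
#' [lue_glmm()]: the centred quadratic temperature columns, natural
#' logs, interaction products, and the site / year-within-site grouping
#' factors.  Records that are incomplete or non-positive under a log
#' transform are dropped (the count is reported).
#'
#' @param composites An `lue_composites` data.frame (or any data.frame
#'   with the raw predictor columns).
#' @param design A [lue_design()].
#' @param temp_center Centring constant for temperature; defaults to the
#'   sample mean of the retained rows.
#' @return A list: `y` (response), `X` (fixed-effects model matrix with
#'   intercept), `groups` (list of grouping factors), `frame` (the
#'   transformed model frame), `temp_center`, `n_dropped`.
#' @export
build_design <- function(composites, design = lue_design(),
                         temp_center = NULL) {
  fr <- .build_frame(composites, design, temp_center)
  X <- stats::model.matrix(
    stats::as.formula(paste("~", .fixed_formula_rhs(design))), fr)
  list(y = fr$lue, X = X,
       groups = list(site = fr$site_id, year_in_site = fr$site_year,
                     year = fr$year_f),
       frame = fr,
       temp_center = attr(fr, "temp_center"),
       n_dropped = attr(fr, "n_dropped"))
}

#' Fit a gamma mixed model for light use efficiency
#'
#' Fits `log E[LUE] = X beta + a_site + a_year|site` with a gamma
#' response distribution, by maximum (not restricted) likelihood with a
#' Laplace approximation over the Gaussian random intercepts, so that
#' AIC/BIC are comparable across fixed-effect structures.  The gamma
#' shape is estimated jointly with the coefficients.
#'
#' @param composites An `lue_composites` data.frame (from
#'   [make_composites()]) or any data.frame with columns `lue`,
#'   `site_id`, `year` and the predictors the design needs.
#' @param design A [lue_design()].
#' @param temp_center Centring constant (degC) for the quadratic
#'   temperature term; defaults to the sample mean.  Stored on the fit
#'   and reused by [predict.lue_glmm()] and [temperature_optimum()].
#' @return An object of class `lue_glmm` with components `beta`,
#'   `beta_se`, `sigma2_site`, `sigma2_year`, `shape`, `loglik`, `df`,
#'   `aic`, `bic`, `n`, `converged`, `blups`, `design`, `temp_center`,
#'   `medians`, the transformed model `frame`, and the underlying
#'   `glmmTMB` object as `fit`.
#' @examples
#' \donttest{
#' net <- generate_site_network(synth_config(n_sites = 6, seed = 3))
#' comp <- make_composites(net$daily)
#' m <- lue_glmm(comp)
#' summary(m)
#' temperature_optimum(m)
#' }
#' @export
lue_glmm <- function(composites, design = lue_design(),
                     temp_center = NULL) {
  fr <- .build_frame(composites, design, temp_center)
  if (design$random != "none") {
    g <- switch(design$random,
                year_in_site = fr$site_id, site_only = fr$site_id,
                year_only = fr$year_f)
    if (nlevels(droplevels(g)) < 2)
      stop("random intercepts need at least 2 groups")
  }
  rhs <- .fixed_formula_rhs(design)
  rnd <- .random_formula_rhs(design)
  n <- nrow(fr)
  if (design$random == "none") {
    # fixed-effects-only gamma GLM: exact IRLS solution, gamma shape by
    # profile maximum likelihood
    fit <- stats::glm(stats::as.formula(paste("lue ~", rhs)), data = fr,
                      family = stats::Gamma(link = "log"),
                      control = stats::glm.control(epsilon = 1e-14,
                                                   maxit = 100))
    co <- summary(fit)$coefficients
    mu <- as.numeric(stats::fitted(fit))
    prof <- function(lshape) {
      s <- exp(lshape)
      sum(stats::dgamma(fr$lue, shape = s, rate = s / mu, log = TRUE))
    }
    op <- stats::optimize(prof, c(-7, 16), maximum = TRUE, tol = 1e-10)
    shape <- exp(op$maximum)
    ll_val <- op$objective
    df <- nrow(co) + 1L
    sig2_site <- 0; sig2_year <- 0
    conv <- isTRUE(fit$converged)
    blups <- NULL
  } else {
    fml <- stats::as.formula(
      paste("lue ~", paste(c(rhs, rnd), collapse = " + ")))
    fit <- glmmTMB::glmmTMB(fml, data = fr,
                            family = stats::Gamma(link = "log"),
                            REML = FALSE)
    sm <- summary(fit)
    co <- sm$coefficients$cond
    vc <- glmmTMB::VarCorr(fit)$cond
    getv <- function(name) {
      v <- vc[[name]]
      if (is.null(v)) 0 else as.numeric(v[1, 1])
    }
    ll <- stats::logLik(fit)
    ll_val <- as.numeric(ll)
    df <- attr(ll, "df")
    shape <- 1 / glmmTMB::sigma(fit)^2
    sig2_site <- getv("site_id")
    sig2_year <- getv("site_year") + getv("year_f")
    conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
    blups <- tryCatch(glmmTMB::ranef(fit)$cond, error = function(e) NULL)
  }

  med_vars <- intersect(c("temp", "vpd", "soil_m", "ci", "td", "fapar",
                          "co2", "elevation", "ppfd"), names(fr))
  medians <- vapply(med_vars, function(v)
    stats::median(fr[[v]], na.rm = TRUE), numeric(1))

  obj <- list(fit = fit, design = design,
              beta = co[, 1], beta_se = co[, 2],
              sigma2_site = sig2_site,
              sigma2_year = sig2_year,
              shape = shape,
              loglik = ll_val, df = df,
              aic = -2 * ll_val + 2 * df,
              bic = -2 * ll_val + df * log(n),
              n = n, converged = conv, blups = blups,
              temp_center = attr(fr, "temp_center"),
              medians = medians, frame = fr,
              n_dropped = attr(fr, "n_dropped"))
  class(obj) <- "lue_glmm"
  obj
}

#' @export
print.lue_glmm <- function(x, ...) {
  cat(sprintf("Gamma mixed model for LUE (log link) -- design '%s'\n",
              x$design$label))
  cat(sprintf("  n = %d windows, %d site(s)%s\n", x$n,
              nlevels(x$frame$site_id),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  fixed effects (link scale):\n")
  print(round(x$beta, 5))
  cat(sprintf("  var(site) = %.5f, var(year|site) = %.5f, shape = %.2f\n",
              x$sigma2_site, x$sigma2_year, x$shape))
  cat(sprintf("  logLik %.2f  df %d  AIC %.1f  BIC %.1f\n",
              x$loglik, x$df, x$aic, x$bic))
  invisible(x)
}

#' @export
summary.lue_glmm <- function(object, ...) {
  z <- object$beta / object$beta_se
  tab <- cbind(Estimate = object$beta, `Std. Error` = object$beta_se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(design = object$design, coefficients = tab,
              sigma2_site = object$sigma2_site,
              sigma2_year = object$sigma2_year,
              shape = object$shape, loglik = object$loglik,
              df = object$df, aic = object$aic, bic = object$bic,
              n = object$n, converged = object$converged,
              temp_center = object$temp_center)
  class(out) <- "summary.lue_glmm"
  out
}

#' @export
print.summary.lue_glmm <- function(x, ...) {
  cat(sprintf("Gamma mixed model for LUE -- design '%s' (n = %d)\n\n",
              x$design$label, x$n))
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("\nRandom intercepts: var(site) = %.5f, var(year|site) = %.5f\n",
              x$sigma2_site, x$sigma2_year))
  cat(sprintf("Gamma shape: %.2f   temperature centred at %.2f degC\n",
              x$shape, x$temp_center))
  cat(sprintf("logLik %.2f  df %d  AIC %.1f  BIC %.1f%s\n",
              x$loglik, x$df, x$aic, x$bic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.lue_glmm <- function(object, ...) object$beta

#' @export
logLik.lue_glmm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

# fixed-effects linear predictor for raw newdata, at the stored centring
.fixed_eta <- function(object, newdata) {
  reg <- .term_registry[object$design$fixed]
  fr <- data.frame(row.names = seq_len(nrow(newdata)))
  if ("temp" %in% names(newdata)) {
    fr$temp_c <- newdata$temp - object$temp_center
    fr$temp_c2 <- fr$temp_c^2
  }
  for (v in c("vpd", "soil_m", "ci", "td", "fapar", "co2", "elevation",
              "ppfd"))
    if (v %in% names(newdata)) fr[[v]] <- newdata[[v]]
  if (!is.null(fr$vpd)) fr$lvpd <- log(fr$vpd)
  if (!is.null(fr$soil_m)) fr$lsm <- log(fr$soil_m)
  if (!is.null(fr$ci)) fr$lci <- log(pmax(fr$ci, .Machine$double.eps))
  if (!is.null(fr$ci) && !is.null(fr$fapar)) fr$ci_fapar <- fr$ci * fr$fapar
  if (!is.null(fr$td) && !is.null(fr$fapar)) fr$td_fapar <- fr$td * fr$fapar
  cols <- unlist(lapply(reg, `[[`, "cols"))
  miss <- setdiff(cols, names(fr))
  if (length(miss))
    stop("newdata lacks variables for term column(s): ",
         paste(miss, collapse = ", "))
  X <- stats::model.matrix(
    stats::as.formula(paste("~", .fixed_formula_rhs(object$design))), fr)
  list(eta = as.numeric(X %*% object$beta), X = X)
}

#' Predict LUE from a fitted gamma mixed model
#'
#' @param object An `lue_glmm` fit.
#' @param newdata Data.frame with the raw predictor columns the design
#'   uses (`temp`, `vpd`, `soil_m`, `ci`, ...); defaults to the model
#'   frame.  For `include_random = TRUE` it must also carry `site_id`
#'   and `year`.
#' @param include_random Add the predicted site and year-within-site
#'   intercepts (BLUPs) on the link scale where the group is known;
#'   unknown groups silently fall back to the fixed-effects prediction.
#' @param type `"response"` (LUE, mol C mol-1 photons) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.lue_glmm <- function(object, newdata = NULL,
                             include_random = FALSE,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    nd <- object$frame
    nd$temp <- nd$temp_c + object$temp_center
    newdata <- nd
    if (include_random) {
      newdata$site_id <- as.character(object$frame$site_id)
      newdata$year <- as.character(object$frame$year_f)
    }
  }
  eta <- .fixed_eta(object, newdata)$eta
  if (include_random && !is.null(object$blups)) {
    bl <- object$blups
    add_re <- function(comp, keys) {
      if (is.null(bl[[comp]])) return(0)
      u <- bl[[comp]][, "(Intercept)"]
      names(u) <- rownames(bl[[comp]])
      out <- u[keys]
      out[is.na(out)] <- 0
      as.numeric(out)
    }
    if (!is.null(newdata$site_id))
      eta <- eta + add_re("site_id", as.character(newdata$site_id))
    if (!is.null(newdata$site_id) && !is.null(newdata$year))
      eta <- eta + add_re("site_year",
                          paste(newdata$site_id, newdata$year, sep = ":"))
    if (!is.null(newdata$year))
      eta <- eta + add_re("year_f", as.character(newdata$year))
  }
  if (type == "response") exp(eta) else eta
}

#' @export
fitted.lue_glmm <- function(object, ...) {
  as.numeric(stats::fitted(object$fit))
}

#' Residuals of a fitted LUE model
#'
#' @param object An `lue_glmm` fit.
#' @param type `"working"` ((y - mu)/mu, the link-scale residual used
#'   for variance partitioning and partial residuals), `"pearson"`,
#'   `"deviance"` or `"response"`.
#' @param ... Unused.
#' @export
residuals.lue_glmm <- function(object, type = c("working", "pearson",
                                                "deviance", "response"),
                               ...) {
  type <- match.arg(type)
  y <- object$frame$lue
  mu <- fitted(object)
  switch(type,
         working = (y - mu) / mu,
         response = y - mu,
         pearson = as.numeric(stats::residuals(object$fit,
                                               type = "pearson")),
         deviance = {
           d <- 2 * ((y - mu) / mu - log(y / mu))
           sign(y - mu) * sqrt(pmax(d, 0))
         })
}

#' Simulate LUE responses from a fitted model
#'
#' Draws gamma deviates at the conditional means (fixed effects plus
#' fitted random intercepts) with the estimated shape.
#'
#' @param object An `lue_glmm` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns, as [stats::simulate()].
#' @export
simulate.lue_glmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- as.data.frame(replicate(
    nsim, stats::rgamma(length(mu), shape = object$shape,
                        rate = object$shape / mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
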