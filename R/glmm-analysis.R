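#' Fit a ladder of candidate designs and rank them by AIC
#'
#' All designs are fitted to the same observation set: rows missing any
#' variable used anywhere in the ladder are dropped first, so the
#' information criteria are comparable.
#'
#' @param composites An `lue_composites` data.frame.
#' @param ladder List of [lue_design()] objects (default:
#'   [default_ladder()]).
#' @param temp_center Optional common temperature centring constant.
#' @return A data.frame of class `lue_ladder` with one row per design:
#'   `model`, `fixed`, `df`, `aic`, `bic`, `loglik`, `converged`, and
#'   `best` flagging the AIC-minimising converged design.  The fitted
#'   objects are kept in `attr(, "fits")`.
#' @export
selection_ladder <- function(composites, ladder = default_ladder(),
                             temp_center = NULL) {
  if (!length(ladder)) stop("empty design ladder")
  common <- .build_frame(composites, ladder, temp_center)
  rows <- attr(common, "rows")
  data_common <- composites[rows, , drop = FALSE]
  tc <- attr(common, "temp_center")
  fits <- lapply(ladder, function(d)
    tryCatch(lue_glmm(data_common, d, temp_center = tc),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "lue_glmm_failure")))
  row1 <- function(f, lab) {
    if (inherits(f, "lue_glmm_failure"))
      data.frame(model = lab, fixed = NA_character_, df = NA_integer_,
                 aic = NA_real_, bic = NA_real_, loglik = NA_real_,
                 converged = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(model = lab,
                 fixed = paste(f$design$fixed, collapse = " + "),
                 df = f$df, aic = f$aic, bic = f$bic, loglik = f$loglik,
                 converged = f$converged, stringsAsFactors = FALSE)
  }
  labs <- names(ladder) %||% vapply(ladder, `[[`, "", "label")
  tab <- do.call(rbind, Map(row1, fits, labs))
  ok <- tab$converged & is.finite(tab$aic)
  tab$best <- FALSE
  if (any(ok)) tab$best[which(ok)[which.min(tab$aic[ok])]] <- TRUE
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "n") <- nrow(common)
  class(tab) <- c("lue_ladder", "data.frame")
  tab
}

#' @export
print.lue_ladder <- function(x, ...) {
  cat(sprintf("Model selection ladder (n = %d common windows)\n",
              attr(x, "n")))
  y <- as.data.frame(x)
  y$aic <- round(y$aic, 1); y$bic <- round(y$bic, 1)
  y$loglik <- round(y$loglik, 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Partition unexplained log-LUE variance into random components
#'
#' Apportions the variance not captured by the fixed effects between
#' sites, years within sites, and the residual, all on the log-link
#' scale.  The residual component is the variance of the working
#' residuals (y - mu)/mu, a link-scale measure of the intra-window
#' noise.
#'
#' @param object An `lue_glmm` fit with `year_in_site` random design.
#' @return Named numeric vector `c(site, year_in_site, residual)`
#'   summing to exactly 1.
#' @export
variance_partition <- function(object) {
  stopifnot(inherits(object, "lue_glmm"))
  if (object$design$random != "year_in_site")
    stop("variance_partition requires the year_in_site random design")
  if (!object$converged)
    warning("variance partition from a non-converged fit")
  s2_res <- stats::var(residuals(object, type = "working"))
  tot <- object$sigma2_site + object$sigma2_year + s2_res
  if (!is.finite(tot) || tot <= 0)
    stop("variance_partition: zero total variance")
  out <- c(site = object$sigma2_site, year_in_site = object$sigma2_year,
           residual = s2_res) / tot
  out / sum(out)
}

#' Conditional response curve for one model variable
#'
#' The fitted LUE response to one predictor with every other numeric
#' variable held at its median and random effects at their reference
#' (zero) level, together with partial residuals: for observation i the
#' link-scale contribution of the variable at its observed value, plus
#' the all-median baseline and the working residual, mapped through the
#' inverse link.
#'
#' @param object An `lue_glmm` fit.
#' @param variable One of the raw predictors used by the design:
#'   `"temp"`, `"vpd"`, `"soil_m"`, `"ci"`, `"td"`, `"fapar"`, `"co2"`,
#'   `"elevation"`, `"ppfd"`.
#' @param n_grid Grid resolution across the observed range.
#' @param level Confidence level of the pointwise band.
#' @return A data.frame of class `lue_response` with columns
#'   `variable`, `x`, `mu`, `lo`, `hi`; partial residuals (x, y) in
#'   `attr(, "partial_residuals")`.
#' @export
conditional_response <- function(object, variable, n_grid = 100,
                                 level = 0.95) {
  stopifnot(inherits(object, "lue_glmm"))
  used <- unique(unlist(lapply(.term_registry[object$design$fixed],
                               `[[`, "raw")))
  if (!variable %in% used)
    stop("variable '", variable, "' is not part of the fitted design")
  fr <- object$frame
  xobs <- if (variable == "temp") fr$temp_c + object$temp_center
          else fr[[variable]]
  grid <- seq(min(xobs), max(xobs), length.out = n_grid)

  base <- as.data.frame(as.list(object$medians))
  nd <- base[rep(1, n_grid), , drop = FALSE]
  nd[[variable]] <- grid
  fe <- .fixed_eta(object, nd)
  eta <- fe$eta
  V <- tryCatch(stats::vcov(object$fit)$cond, error = function(e) NULL)
  if (!is.null(V) && all(colnames(fe$X) %in% colnames(V))) {
    Vs <- V[colnames(fe$X), colnames(fe$X)]
    se <- sqrt(pmax(rowSums((fe$X %*% Vs) * fe$X), 0))
  } else se <- rep(NA_real_, n_grid)
  zq <- stats::qnorm(1 - (1 - level) / 2)

  # partial residuals: all-median baseline + the variable's own
  # link-scale contribution at each observation + working residual
  nd_obs <- base[rep(1, nrow(fr)), , drop = FALSE]
  nd_obs[[variable]] <- xobs
  eta_obs <- .fixed_eta(object, nd_obs)$eta
  pr <- exp(eta_obs + residuals(object, type = "working"))

  out <- data.frame(variable = variable, x = grid, mu = exp(eta),
                    lo = exp(eta - zq * se), hi = exp(eta + zq * se),
                    stringsAsFactors = FALSE)
  attr(out, "partial_residuals") <- data.frame(x = xobs, y = pr)
  class(out) <- c("lue_response", "data.frame")
  out
}

#' Temperature optimum implied by the fitted quadratic
#'
#' The vertex of the fitted centred quadratic in temperature,
#' `temp_center - beta1 / (2 * beta2)`, i.e. the daytime temperature at
#' which the conditional LUE response peaks.
#'
#' @param object An `lue_glmm` fit whose design includes `temp_poly2`.
#' @return The optimum in degC.  If the quadratic curves upward
#'   (`beta2 >= 0`) there is no interior optimum: `Inf` is returned
#'   with attribute `flagged = TRUE`.
#' @export
temperature_optimum <- function(object) {
  stopifnot(inherits(object, "lue_glmm"))
  if (!"temp_poly2" %in% object$design$fixed)
    stop("temperature_optimum needs the quadratic temperature term")
  b1 <- object$beta[["temp_c"]]
  b2 <- object$beta[["temp_c2"]]
  if (!is.finite(b2) || b2 >= 0)
    return(structure(Inf, flagged = TRUE))
  object$temp_center - b1 / (2 * b2)
}

#' Leave-one-site-out cross-validation of the fixed-effects model
#'
#' For each site, a fixed-effects-only gamma GLM (log link) with the
#' design's fixed terms is trained on all other sites and used to
#' predict the held-out site; pooled performance is summarised over all
#' held-out rows.  A fixed-only in-sample fit on the full data is
#' reported as the companion metric.
#'
#' @param composites An `lue_composites` data.frame.
#' @param design A [lue_design()]; its random part is ignored.
#' @param r2 `"pearson"` (squared Pearson correlation of observed and
#'   predicted, the default) or `"ss"` (1 - SSE/SST).
#' @param temp_center Optional fixed temperature centring.
#' @return List with `predictions` (site_id, observed, predicted),
#'   `r2_cv`, `r2_fixed` (in-sample fixed-only), and `skipped`
#'   (sites whose training fold failed).
#' @export
loo_site_cv <- function(composites, design = lue_design(),
                        r2 = c("pearson", "ss"), temp_center = NULL) {
  r2 <- match.arg(r2)
  fr <- .build_frame(composites, design, temp_center)
  if (nlevels(droplevels(fr$site_id)) < 3)
    stop("leave-one-site-out CV needs at least 3 sites")
  fml <- stats::as.formula(paste("lue ~", .fixed_formula_rhs(design)))
  r2fun <- function(obs, pred) {
    if (r2 == "pearson") stats::cor(obs, pred)^2
    else 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
  preds <- list(); skipped <- character()
  for (s in levels(droplevels(fr$site_id))) {
    train <- fr[fr$site_id != s, , drop = FALSE]
    test <- fr[fr$site_id == s, , drop = FALSE]
    g <- tryCatch(stats::glm(fml, data = train,
                             family = stats::Gamma(link = "log")),
                  error = function(e) NULL, warning = function(w) {
                    withCallingHandlers(
                      stats::glm(fml, data = train,
                                 family = stats::Gamma(link = "log")),
                      warning = function(w) invokeRestart("muffleWarning"))
                  })
    if (is.null(g) || !g$converged) { skipped <- c(skipped, s); next }
    preds[[s]] <- data.frame(
      site_id = s, observed = test$lue,
      predicted = as.numeric(stats::predict(g, test, type = "response")),
      stringsAsFactors = FALSE)
  }
  if (!length(preds)) stop("every training fold failed")
  pr <- do.call(rbind, preds); rownames(pr) <- NULL
  g_all <- stats::glm(fml, data = fr, family = stats::Gamma(link = "log"))
  list(predictions = pr,
       r2_cv = r2fun(pr$observed, pr$predicted),
       r2_fixed = r2fun(fr$lue,
                        as.numeric(stats::fitted(g_all))),
       skipped = skipped)
}

#' Plot conditional response curves of a fitted LUE model
#'
#' Base-graphics panels of the conditional LUE response to each raw
#' variable in the design, with partial residuals.
#'
#' @param x An `lue_glmm` fit.
#' @param variables Raw variables to plot; defaults to all in the design.
#' @param n_grid Grid resolution.
#' @param points Draw partial residuals.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lue_glmm <- function(x, variables = NULL, n_grid = 100,
                          points = TRUE, ...) {
  used <- unique(unlist(lapply(.term_registry[x$design$fixed],
                               `[[`, "raw")))
  variables <- variables %||% used
  variables <- intersect(variables, used)
  if (!length(variables)) stop("no plottable variables in the design")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(variables)),
                       mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  labs <- c(temp = "Daytime temperature (degC)", vpd = "VPD (Pa)",
            soil_m = "Soil moisture (fraction)",
            ci = "Cloudiness index", td = "Diffuse transmittance",
            fapar = "fAPAR", co2 = "CO2 (umol mol-1)",
            elevation = "Elevation (m)", ppfd = "PPFD (mol m-2 d-1)")
  for (v in variables) {
    rc <- conditional_response(x, v, n_grid)
    pres <- attr(rc, "partial_residuals")
    ylim <- if (points) range(c(rc$mu, stats::quantile(pres$y,
                                                       c(0.005, 0.995))))
            else range(c(rc$lo, rc$hi), finite = TRUE)
    graphics::plot(rc$x, rc$mu, type = "n", ylim = ylim,
                   xlab = labs[[v]] %||% v,
                   ylab = "LUE (mol C mol-1 photons)", ...)
    if (points)
      graphics::points(pres$x, pres$y, pch = 16, cex = 0.3,
                       col = grDevices::adjustcolor("grey40", 0.4))
    if (all(is.finite(rc$lo)))
      graphics::polygon(c(rc$x, rev(rc$x)), c(rc$lo, rev(rc$hi)),
                        border = NA,
                        col = grDevices::adjustcolor("steelblue", 0.3))
    graphics::lines(rc$x, rc$mu, col = "steelblue4", lwd = 2)
  }
  invisible(x)
}
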