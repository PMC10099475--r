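#' Beer-Lambert fAPAR from leaf area index
#'
#' `fAPAR = 1 - exp(-k * LAI)`: light interception approximated as an
#' exponential function of leaf area.
#'
#' @param lai Leaf area index (m2 m-2), >= 0.
#' @param k Extinction coefficient (default 0.5).
#' @return Fraction in \[0, 1).
#' @examples
#' fapar_from_lai(2)  # 1 - exp(-1)
#' @export
fapar_from_lai <- function(lai, k = 0.5) {
  if (any(is.finite(lai) & lai < 0)) stop("lai must be nonnegative")
  if (k <= 0) stop("k must be positive")
  1 - exp(-k * lai)
}

#' Apply the empirical compositing design to a model's GPP output
#'
#' Substitutes a model's simulated GPP (and, where LAI is supplied, its
#' Beer-Lambert fAPAR) into the compositing pipeline while keeping the
#' observation-defined windows: the quality filters, growing season and
#' 15-day windows are those of the forcing data, and the forcing's PAR
#' is the common denominator, so model LUE is directly comparable with
#' the data-derived LUE.
#'
#' @param model_output Data.frame with columns `model`, `site_id`,
#'   `date`, `gpp_sim` (gC m-2 d-1) and `lai_sim` and/or `fapar_sim`.
#' @param daily The forcing daily table (as passed to
#'   [make_composites()]).
#' @param thresholds A [filter_thresholds()] object.
#' @param k Extinction coefficient for [fapar_from_lai()].
#' @param composites Optional precomputed forcing composites (from
#'   [make_composites()] on `daily` with the same thresholds); avoids
#'   recomputation.
#' @return Named list (one element per model) of `lue_composites`
#'   data.frames in which `lue`, `fapar` carry the model's values;
#'   models with no complete window are dropped with a warning and
#'   recorded in `attr(, "excluded")`.
#' @export
model_lue_composites <- function(model_output, daily,
                                 thresholds = filter_thresholds(),
                                 k = 0.5, composites = NULL) {
  need <- c("model", "site_id", "date", "gpp_sim")
  miss <- setdiff(need, names(model_output))
  if (length(miss))
    stop("model_output lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(model_output$fapar_sim) && is.null(model_output$lai_sim))
    stop("model_output needs lai_sim or fapar_sim")
  if (is.null(composites))
    composites <- make_composites(daily, thresholds)
  memb <- attr(composites, "membership")
  if (is.null(memb) || nrow(memb) == 0)
    stop("forcing data yield no composite windows")
  ppfd_daily <- data.frame(site_id = daily$site_id, date = daily$date,
                           ppfd = ppfd_from_shortwave(daily$sw_in))

  out <- list(); excluded <- character()
  for (m in unique(model_output$model)) {
    mo <- model_output[model_output$model == m, , drop = FALSE]
    if (is.null(mo$fapar_sim) || all(!is.finite(mo$fapar_sim)))
      mo$fapar_sim <- fapar_from_lai(mo$lai_sim, k)
    key_m <- paste(mo$site_id, mo$date)
    key_w <- paste(memb$site_id, memb$date)
    idx <- match(key_w, key_m)
    d <- data.frame(site_id = memb$site_id, date = memb$date,
                    window_index = memb$window_index,
                    gpp = mo$gpp_sim[idx], fapar = mo$fapar_sim[idx],
                    ppfd = ppfd_daily$ppfd[match(key_w,
                      paste(ppfd_daily$site_id, ppfd_daily$date))])
    # keep only windows fully covered by this model's output
    wkey <- paste(d$site_id, d$window_index)
    full <- stats::ave(as.numeric(is.finite(d$gpp) & is.finite(d$fapar) &
                                    d$fapar > 0),
                       wkey, FUN = mean) == 1
    d <- d[full, , drop = FALSE]
    if (nrow(d) == 0) { excluded <- c(excluded, m); next }
    wkey <- factor(paste(d$site_id, d$window_index),
                   levels = unique(paste(d$site_id, d$window_index)))
    msum <- function(v) as.numeric(rowsum(v, wkey, reorder = FALSE))
    nday <- as.numeric(table(wkey)[levels(wkey)])
    first <- !duplicated(wkey)
    sim <- data.frame(site_id = d$site_id[first],
                      window_index = d$window_index[first],
                      lue_sim = (msum(d$gpp) / .MOLAR_MASS_C) /
                        (msum(d$ppfd) * msum(d$fapar) / nday),
                      fapar_sim = msum(d$fapar) / nday,
                      gpp_sim = msum(d$gpp) / nday,
                      stringsAsFactors = FALSE)
    cm <- merge(as.data.frame(composites), sim,
                by = c("site_id", "window_index"), sort = FALSE)
    if (nrow(cm) == 0) { excluded <- c(excluded, m); next }
    cm$gpp_obs <- cm$lue * cm$ppfd * cm$fapar * .MOLAR_MASS_C
    cm$lue <- cm$lue_sim
    cm$fapar <- cm$fapar_sim
    cm$gpp_sim <- cm$gpp_sim
    cm$lue_sim <- NULL; cm$fapar_sim <- NULL
    class(cm) <- c("lue_composites", "data.frame")
    out[[m]] <- cm
  }
  if (length(excluded))
    warning("model(s) with no complete window excluded: ",
            paste(excluded, collapse = ", "))
  attr(out, "excluded") <- excluded
  out
}

#' Fit the common empirical design to every model of an ensemble
#'
#' Fits one [lue_glmm()] with a common design to each model's composite
#' LUE and extracts its conditional response curves, so the shape,
#' strength and sign of each model's environmental dependencies can be
#' compared against the data-derived fit.  Per-model failures are
#' isolated: they never abort the ensemble.
#'
#' @param model_composites Named list of `lue_composites` data.frames,
#'   typically from [model_lue_composites()].
#' @param design Common [lue_design()].
#' @param variables Raw variables for the response curves.
#' @param temp_center Optional common temperature centring.
#' @param n_grid Grid resolution of the curves.
#' @return A list of class `lue_ensemble`: per model, `fit` (an
#'   `lue_glmm` or NULL), `converged`, `error` (message or NA), and
#'   `curves` (named list of `lue_response` data.frames).
#' @export
ensemble_fit <- function(model_composites, design = lue_design(),
                         variables = c("temp", "vpd", "soil_m", "ci"),
                         temp_center = NULL, n_grid = 100) {
  if (!length(model_composites)) stop("empty model set")
  if (is.null(names(model_composites)))
    names(model_composites) <- paste0("model", seq_along(model_composites))
  out <- lapply(names(model_composites), function(m) {
    fit <- tryCatch(lue_glmm(model_composites[[m]], design,
                             temp_center = temp_center),
                    error = function(e)
                      structure(conditionMessage(e), class = "err"))
    if (inherits(fit, "err"))
      return(list(model = m, fit = NULL, converged = FALSE,
                  error = unclass(fit), curves = list()))
    curves <- lapply(variables, function(v)
      tryCatch(conditional_response(fit, v, n_grid),
               error = function(e) NULL))
    names(curves) <- variables
    list(model = m, fit = fit, converged = fit$converged,
         error = NA_character_, curves = curves[!vapply(curves, is.null,
                                                        TRUE)])
  })
  names(out) <- names(model_composites)
  class(out) <- "lue_ensemble"
  out
}

#' @export
print.lue_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d model fit(s):\n", length(x)))
  for (m in names(x))
    cat(sprintf("  %-12s %s\n", m,
                if (is.null(x[[m]]$fit)) paste("failed:", x[[m]]$error)
                else if (x[[m]]$converged) "converged"
                else "fitted (convergence warning)"))
  invisible(x)
}

#' Nash-Sutcliffe model efficiency
#'
#' One minus the ratio of the mean squared observation-simulation error
#' to the variance of the observations: 1 for a perfect match, 0 for a
#' model no better than the observed mean, unbounded below.
#'
#' @param observed,simulated Equal-length numeric vectors (n >= 2);
#'   pairs with missing values are dropped.
#' @return Dimensionless efficiency <= 1.
#' @examples
#' nash_sutcliffe(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
nash_sutcliffe <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stop("observed and simulated must have equal length")
  ok <- is.finite(observed) & is.finite(simulated)
  o <- observed[ok]; s <- simulated[ok]
  if (length(o) < 2) stop("need at least 2 complete pairs")
  sst <- sum((o - mean(o))^2)
  if (sst == 0) stop("observed series is constant; NSE undefined")
  1 - sum((o - s)^2) / sst
}
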