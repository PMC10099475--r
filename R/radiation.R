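#' Convert daily-mean shortwave radiation to daily photon flux
#'
#' Uses the standard conversion factor of 2.04 umol photosynthetic
#' photons per joule of shortwave energy.
#'
#' @param sw_in Daily mean downwelling shortwave radiation (W m-2), >= 0.
#' @return Photosynthetic photon flux density (mol photons m-2 d-1).
#' @examples
#' ppfd_from_shortwave(200)  # 35.2512
#' @export
ppfd_from_shortwave <- function(sw_in) {
  if (any(is.finite(sw_in) & sw_in < 0))
    stop("sw_in must be nonnegative")
  sw_in * 2.04e-6 * 86400
}

#' Cloudiness index
#'
#' `CI = 1 - S_t / S_o`: the complement of atmospheric transmittance,
#' a proxy for the diffuse fraction of incident radiation.
#'
#' @param s_t Surface shortwave radiation (W m-2).
#' @param s_o Potential (top-of-atmosphere) shortwave radiation (W m-2).
#' @return Cloudiness index in \[0, 1\]; `NA` where `s_o <= 0` (the
#'   record is undefined and callers should drop it from CI-dependent
#'   terms).
#' @examples
#' cloudiness_index(300, 400)  # 0.25
#' @export
cloudiness_index <- function(s_t, s_o) {
  ifelse(is.finite(s_o) & s_o > 0, 1 - s_t / s_o, NA_real_)
}

#' Diffuse transmittance from total transmittance (Bristow relation)
#'
#' `T_d = T_T * (1 - exp(0.6 * (1 - B / T_T) / (B - 0.4)))`, the
#' one-parameter empirical mapping from total to diffuse atmospheric
#' transmittance.  At `T_T = B` the diffuse share is zero; as
#' `T_T -> 0` all transmitted radiation is diffuse.
#'
#' @param t_t Total transmittance `S_t / S_o`, in (0, 1].
#' @param B Shape coefficient, in (0.4, 1].
#' @return Diffuse transmittance, bounded by `0 <= T_d <= T_T`.
#' @examples
#' diffuse_transmittance(0.5, 0.889)  # ~0.3075
#' @export
diffuse_transmittance <- function(t_t, B) {
  if (any(is.finite(t_t) & t_t <= 0)) stop("t_t must be positive")
  if (length(B) != 1 || !is.finite(B) || B <= 0.4 || B > 1)
    stop("B must be a scalar in (0.4, 1]")
  td <- t_t * (1 - exp(0.6 * (1 - B / t_t) / (B - 0.4)))
  pmin(pmax(td, 0), t_t)
}

#' Fit the Bristow diffuse-transmittance coefficient
#'
#' Least-squares estimate of the shape coefficient `B` from paired
#' observations of diffuse and total transmittance, by bounded
#' one-dimensional minimisation of the residual sum of squares over
#' `B` in (0.4, 1].
#'
#' @param t_d_obs,t_t_obs Paired diffuse and total transmittances,
#'   each in (0, 1], length >= 10.
#' @return A list of class `bristow_fit`: `B` (estimate), `se`
#'   (large-sample standard error from the curvature of the loss),
#'   `n`, `rss`, and `boundary` (TRUE if the optimum sits against a
#'   bound of the admissible interval).
#' @examples
#' tt <- runif(200, 0.1, 0.95)
#' td <- diffuse_transmittance(tt, 0.75)
#' fit_bristow(td, tt)$B  # ~0.75
#' @export
fit_bristow <- function(t_d_obs, t_t_obs) {
  keep <- is.finite(t_d_obs) & is.finite(t_t_obs) &
    t_t_obs > 0 & t_t_obs <= 1 & t_d_obs > 0 & t_d_obs <= 1
  t_d <- t_d_obs[keep]; t_t <- t_t_obs[keep]
  if (length(t_d) < 10)
    stop("fit_bristow needs at least 10 valid (t_d, t_t) pairs")
  sse <- function(B) sum((t_d - diffuse_transmittance(t_t, B))^2)
  lo <- 0.4 + 1e-6
  opt <- stats::optimize(sse, c(lo, 1), tol = 1e-8)
  B <- opt$minimum
  boundary <- (B - lo) < 1e-4 || (1 - B) < 1e-4
  if (boundary) warning("Bristow fit hit the boundary of (0.4, 1]")
  # curvature-based standard error: var(B) ~ 2*sigma^2 / d2SSE/dB2
  h <- 1e-4
  d2 <- (sse(min(B + h, 1)) - 2 * sse(B) + sse(max(B - h, lo))) / h^2
  s2 <- opt$objective / max(length(t_d) - 1, 1)
  se <- if (is.finite(d2) && d2 > 0) sqrt(2 * s2 / d2) else NA_real_
  structure(list(B = B, se = se, n = length(t_d), rss = opt$objective,
                 boundary = boundary),
            class = "bristow_fit")
}

#' @export
print.bristow_fit <- function(x, ...) {
  cat(sprintf("Bristow diffuse-transmittance fit: B = %.4f (se %.4f, n = %d)%s\n",
              x$B, x$se, x$n, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Gap-fill missing diffuse photon flux with the Bristow relation
#'
#' Fills missing `ppfd_dif` values by predicting diffuse transmittance
#' from each day's total transmittance (`sw_in / sw_in_pot`) via
#' [diffuse_transmittance()], converting back to a photon flux.
#' Observed values are never overwritten.
#'
#' @param records A daily data.frame with columns `sw_in`, `sw_in_pot`
#'   and `ppfd_dif` (umol m-2 s-1, NA where unobserved).
#' @param B Bristow coefficient, typically from [fit_bristow()].
#' @return `records` with `ppfd_dif` completed and a logical column
#'   `ppfd_dif_filled` marking imputed values.
#' @export
gapfill_diffuse <- function(records, B) {
  stopifnot(all(c("sw_in", "sw_in_pot", "ppfd_dif") %in% names(records)))
  miss <- !is.finite(records$ppfd_dif)
  t_t <- cloudiness_index(records$sw_in, records$sw_in_pot)
  t_t <- 1 - t_t   # total transmittance
  fill <- miss & is.finite(t_t) & t_t > 0
  td <- diffuse_transmittance(t_t[fill], B)
  records$ppfd_dif[fill] <- td * records$sw_in_pot[fill] * 2.04
  records$ppfd_dif[miss & !fill] <- 0
  records$ppfd_dif_filled <- miss
  records
}
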