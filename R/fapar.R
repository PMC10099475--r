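#' Interpolate sparse fAPAR observations to a daily series
#'
#' Reproduces the standard treatment of remotely sensed fAPAR at flux
#' sites: saturated values (exactly 1.0) and likely outliers (more than
#' three times the inter-quartile range from the median) are discarded,
#' and a cubic smoothing spline is fitted through the survivors to give
#' daily estimates, clipped to (0, 1].
#'
#' @param dates Dates (or numeric day indices) of the observations.
#' @param values Observed fAPAR fractions; NAs are ignored.
#' @param out_dates Dates at which daily values are wanted.
#' @param df_per_year Effective degrees of freedom of the spline per
#'   year of record (default 25, about one basis function per 15 days,
#'   the compositing scale, so green-up and senescence corners are
#'   tracked rather than rounded off).  `NULL` selects the smoothness
#'   by generalized cross-validation instead.
#' @return Numeric vector of daily fAPAR along `out_dates`.  Errors if
#'   fewer than 4 observations survive filtering (the site should be
#'   excluded).
#' @examples
#' d <- seq(as.Date("2001-01-01"), by = 4, length.out = 40)
#' f <- 0.4 + 0.3 * sin(seq(0, 2, length.out = 40))
#' daily <- interpolate_fapar(d, f, seq(min(d), max(d), by = "day"))
#' @export
interpolate_fapar <- function(dates, values, out_dates,
                              df_per_year = 25) {
  ok <- is.finite(values)
  x <- as.numeric(dates)[ok]
  y <- values[ok]
  keep <- y < 1
  med <- stats::median(y[keep])
  iqr <- stats::IQR(y[keep])
  if (is.finite(iqr) && iqr > 0) keep <- keep & abs(y - med) <= 3 * iqr
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4)
    stop("interpolate_fapar: fewer than 4 retained observations")
  xo <- as.numeric(out_dates)
  if (stats::sd(y) < 1e-10) return(rep(y[1], length(xo)))
  if (is.null(df_per_year)) {
    sp <- stats::smooth.spline(x, y, cv = FALSE)
  } else {
    span_years <- max(diff(range(x)) / 365.25, 1 / 365.25)
    df <- min(max(4, round(df_per_year * span_years)),
              length(unique(x)) - 1)
    sp <- stats::smooth.spline(x, y, df = df)
  }
  out <- stats::predict(sp, xo)$y
  pmin(pmax(out, 1e-4), 1)
}
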