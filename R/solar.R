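#' Daily-mean potential (top-of-atmosphere) shortwave radiation
#'
#' Computes the 24-h mean extraterrestrial shortwave irradiance from
#' standard solar geometry: solar constant 1361 W m-2, inverse-square
#' correction for the Earth--Sun distance, solar declination, and the
#' sunset hour angle.  This is the quantity FLUXNET distributes as
#' `SW_IN_POT` and the denominator of the cloudiness index.
#'
#' @param latitude Latitude in decimal degrees, in \[-90, 90\].
#' @param day_of_year Integer day of year, in \[1, 366\].  `latitude` and
#'   `day_of_year` are recycled against each other.
#' @return Daily mean potential radiation (W m-2); 0 during polar night.
#' @examples
#' potential_radiation(45, 172)   # northern mid-latitude summer solstice
#' potential_radiation(80, 355)   # polar night: 0
#' @export
potential_radiation <- function(latitude, day_of_year) {
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90))
    stop("latitude must be in [-90, 90]")
  if (any(!is.finite(day_of_year)) || any(day_of_year < 1) ||
      any(day_of_year > 366))
    stop("day_of_year must be in [1, 366]")

  s0 <- 1361                                # solar constant, W m-2
  phi <- latitude * pi / 180
  g <- 2 * pi * day_of_year / 365
  dr <- 1 + 0.033 * cos(g)                  # inverse-square distance factor
  delta <- 0.409 * sin(g - 1.39)            # declination, rad
  # sunset hour angle; clamp handles polar day (>= 1) and night (<= -1)
  x <- -tan(phi) * tan(delta)
  ws <- acos(pmin(pmax(x, -1), 1))
  out <- (s0 * dr / pi) *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  pmax(out, 0)
}
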