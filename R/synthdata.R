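#' Configuration for the synthetic flux-site network generator
#'
#' Bundles the ground-truth parameters and structural knobs of the
#' synthetic data generator.  The generator emulates the statistical
#' structure of daily FLUXNET-style records: seasonal radiation and
#' temperature cycles, VPD log-linearly coupled to temperature with
#' independent synoptic noise, bucket-model soil moisture, bounded
#' autoregressive cloudiness, sparse noisy fAPAR observations,
#' multiplicative gamma noise on GPP, and lognormal site and
#' year-within-site random intercepts on LUE.
#'
#' @param n_sites Number of sites (>= 1).
#' @param years_per_site Whole calendar years simulated per site.
#' @param latitude_range Length-2 numeric, degrees north; site latitudes
#'   are drawn uniformly in this range.
#' @param true_coefficients Named numeric vector of the generating
#'   fixed effects on log LUE: `intercept`, `temp` (per degC, on
#'   temperature centred at `temp_center`), `temp2` (per degC^2),
#'   `log_vpd`, `log_soil_m`, `log_ci`.
#' @param temp_center Centring constant (degC) at which the quadratic
#'   temperature truth is parameterised.
#' @param sd_site Standard deviation of site random intercepts (log scale).
#' @param sd_year Standard deviation of year-within-site intercepts
#'   (log scale).
#' @param gamma_shape Shape of the mean-1 multiplicative gamma noise on
#'   daily GPP.  `Inf` switches the noise off (noise-free generation).
#' @param lue_process_sd Stationary log-scale standard deviation of a
#'   slowly varying multiplicative LUE process noise (autoregressive,
#'   coefficient `lue_process_ar`).  This emulates the unexplained
#'   intra-annual LUE variation that dominates the residual term of the
#'   mixed model at the 15-day scale; unlike day-independent gamma
#'   noise it does not average out within compositing windows.  Set to
#'   0 for noise-free generation.
#' @param lue_process_ar Daily autoregression coefficient of the LUE
#'   process noise (0.6 gives a ~2-day correlation length).
#' @param bristow_b Bristow shape coefficient used to derive the diffuse
#'   radiation stream.
#' @param gap_rate Mean daily gap-filled fraction.  Gap-filling is
#'   generated as a low beta-distributed baseline plus clustered outage
#'   episodes so that days exceeding the 50% quality threshold arrive in
#'   runs, as instrument failures do.
#' @param fapar_obs_interval_days Days between fAPAR observations
#'   (4 emulates MODIS FPAR revisit).
#' @param fapar_noise_sd Lognormal sd of fAPAR observation noise.
#' @param fapar_outlier_rate,fapar_unity_rate Rates of contaminated
#'   (strongly biased-low) and saturated (exactly 1.0) fAPAR
#'   observations.
#' @param diffuse_site_frac Fraction of sites equipped with diffuse
#'   radiation instrumentation (others report `ppfd_dif` as missing).
#' @param cloud_ar_coef,cloud_bounds Daily cloudiness autoregression
#'   coefficient and admissible cloudiness-index range.
#' @param start_year First simulated calendar year.
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `synth_config`.
#' @seealso [generate_site_network()]
#' @export
synth_config <- function(n_sites = 12,
                         years_per_site = 3,
                         latitude_range = c(30, 55),
                         true_coefficients = c(intercept = -1.43,
                                               temp = 0.03,
                                               temp2 = -0.0015,
                                               log_vpd = -0.35,
                                               log_soil_m = 0.15,
                                               log_ci = 0.10),
                         temp_center = 15,
                         sd_site = 0.15,
                         sd_year = 0.08,
                         gamma_shape = 25,
                         lue_process_sd = 0.42,
                         lue_process_ar = 0.6,
                         bristow_b = 0.889,
                         gap_rate = 0.15,
                         fapar_obs_interval_days = 4,
                         fapar_noise_sd = 0.05,
                         fapar_outlier_rate = 0.02,
                         fapar_unity_rate = 0.01,
                         diffuse_site_frac = 0.4,
                         cloud_ar_coef = 0.7,
                         cloud_bounds = c(0.02, 0.95),
                         start_year = 2001,
                         seed = 1L) {
  stopifnot(n_sites >= 1, years_per_site >= 1,
            length(latitude_range) == 2,
            gamma_shape > 0, lue_process_sd >= 0,
            lue_process_ar >= 0, lue_process_ar < 1,
            sd_site >= 0, sd_year >= 0,
            gap_rate >= 0, gap_rate < 1,
            fapar_obs_interval_days >= 1,
            bristow_b > 0.4, bristow_b <= 1)
  need <- c("intercept", "temp", "temp2", "log_vpd", "log_soil_m", "log_ci")
  if (!all(need %in% names(true_coefficients)))
    stop("true_coefficients must carry names: ",
         paste(need, collapse = ", "))
  cfg <- list(n_sites = as.integer(n_sites),
              years_per_site = as.integer(years_per_site),
              latitude_range = sort(as.numeric(latitude_range)),
              true_coefficients = true_coefficients[need],
              temp_center = temp_center,
              sd_site = sd_site, sd_year = sd_year,
              gamma_shape = gamma_shape,
              lue_process_sd = lue_process_sd,
              lue_process_ar = lue_process_ar,
              bristow_b = bristow_b,
              gap_rate = gap_rate,
              fapar_obs_interval_days = as.integer(fapar_obs_interval_days),
              fapar_noise_sd = fapar_noise_sd,
              fapar_outlier_rate = fapar_outlier_rate,
              fapar_unity_rate = fapar_unity_rate,
              diffuse_site_frac = diffuse_site_frac,
              cloud_ar_coef = cloud_ar_coef,
              cloud_bounds = cloud_bounds,
              start_year = as.integer(start_year),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic flux-network configuration\n")
  cat(sprintf("  %d site(s) x %d year(s), latitudes %.1f-%.1f degN, seed %d\n",
              x$n_sites, x$years_per_site,
              x$latitude_range[1], x$latitude_range[2], x$seed))
  cat("  true log-LUE coefficients:\n")
  print(x$true_coefficients)
  cat(sprintf("  sd_site %.3f, sd_year %.3f, gamma shape %s, gap rate %.2f\n",
              x$sd_site, x$sd_year, format(x$gamma_shape), x$gap_rate))
  invisible(x)
}

# centred 15-day running mean, truncated at the series ends
.smooth15 <- function(x, width = 15L) {
  n <- length(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# stationary AR(1) series with innovation sd `sd` and coefficient `phi`
ar1_series <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd)
  e[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

# clustered daily gap-filled fractions: beta baseline + outage episodes
gapfill_series <- function(n, gap_rate) {
  if (gap_rate <= 0) return(numeric(n))
  episode_mean <- 0.775
  episode_len <- 5
  n_epi <- stats::rpois(1, 3 * n / 365)
  base_mean <- max(gap_rate - min(n_epi * episode_len / n, 0.5) * episode_mean,
                   0.01)
  g <- stats::rbeta(n, 2, 2 * (1 - base_mean) / base_mean)
  if (n_epi > 0) {
    starts <- sample.int(n, n_epi, replace = TRUE)
    lens <- 1 + stats::rgeom(n_epi, 1 / episode_len)
    for (k in seq_len(n_epi)) {
      idx <- starts[k]:min(starts[k] + lens[k] - 1, n)
      g[idx] <- stats::runif(length(idx), 0.55, 1)
    }
  }
  pmin(g, 1)
}

#' Generate a synthetic multi-site daily dataset with known ground truth
#'
#' Simulates daily records for a network of flux sites under the LUE
#' model `GPP = LUE x fAPAR x PPFD`, where log LUE follows the
#' generating fixed effects in `config$true_coefficients` plus site and
#' year-within-site random intercepts, and daily GPP carries mean-1
#' multiplicative gamma noise.  Shortwave radiation is derived from
#' solar geometry and a bounded autoregressive cloudiness index; the
#' diffuse photon flux follows the Bristow diffuse-transmittance
#' relation with coefficient `config$bristow_b`.
#'
#' Randomness is organised as one named stream per site derived from the
#' global seed, so identical configurations give byte-identical output.
#'
#' @param config A [synth_config()] object.
#' @return A list of class `lue_network` with elements
#'   \describe{
#'     \item{daily}{data.frame of daily site records (`site_id`, `date`,
#'       `gpp` gC m-2 d-1, `sw_in`, `sw_in_pot` W m-2, `ppfd_dif`
#'       umol m-2 s-1 or NA, `ta_day` degC, `vpd_day` Pa, `co2`
#'       umol mol-1, `soil_m` fraction, `fapar_obs` fraction or NA,
#'       `gapfill_frac`, `elevation` m).}
#'     \item{truth}{data.frame of generating quantities (`lue_true`
#'       mol C mol-1 photons, `fapar_true`, `site_intercept`,
#'       `year_intercept` on the log scale, `in_growing_season`).}
#'     \item{sites}{per-site attributes (latitude, elevation,
#'       diffuse instrumentation flag).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' net <- generate_site_network(synth_config(n_sites = 2, seed = 42))
#' head(net$daily)
#' @export
generate_site_network <- function(config) {
  if (!inherits(config, "synth_config"))
    stop("config must be a synth_config object")
  cf <- config
  set.seed(cf$seed)
  lat <- stats::runif(cf$n_sites, cf$latitude_range[1], cf$latitude_range[2])
  elev <- stats::runif(cf$n_sites, 0, 1500)
  fmax <- stats::runif(cf$n_sites, 0.6, 0.9)
  ci_base <- stats::runif(cf$n_sites, 0.25, 0.45)
  a_site <- stats::rnorm(cf$n_sites, 0, cf$sd_site)
  has_dif <- stats::runif(cf$n_sites) < cf$diffuse_site_frac
  site_seed <- sample.int(.Machine$integer.max - 1L, cf$n_sites)
  site_id <- sprintf("SYN%03d", seq_len(cf$n_sites))

  beta <- cf$true_coefficients
  noise_free <- !is.finite(cf$gamma_shape)
  daily <- vector("list", cf$n_sites)
  truth <- vector("list", cf$n_sites)

  for (i in seq_len(cf$n_sites)) {
    set.seed(site_seed[i])
    dates <- seq(as.Date(sprintf("%d-01-01", cf$start_year)),
                 as.Date(sprintf("%d-12-31",
                                 cf$start_year + cf$years_per_site - 1L)),
                 by = "day")
    n <- length(dates)
    doy <- as.POSIXlt(dates)$yday + 1
    year <- as.POSIXlt(dates)$year + 1900
    t_years <- as.numeric(dates - dates[1]) / 365.25

    sw_in_pot <- potential_radiation(lat[i], doy)

    # cloudiness: seasonal baseline + persistent synoptic component +
    # fast daily component with the configured AR coefficient, clipped
    # to the admissible range
    ci <- ci_base[i] + 0.08 * cos(2 * pi * (doy - 15) / 365) +
      ar1_series(n, 0.93, 0.02) + ar1_series(n, cf$cloud_ar_coef, 0.015)
    ci <- pmin(pmax(ci, cf$cloud_bounds[1]), cf$cloud_bounds[2])
    sw_in <- (1 - ci) * sw_in_pot

    # daytime air temperature: lapse-adjusted seasonal sinusoid with
    # synoptically persistent anomalies (temperature anomalies persist
    # longer than humidity anomalies; ~10-day e-folding, stationary
    # sd ~1.3 degC)
    ta_mean <- 28 - 0.45 * lat[i] - 0.0065 * elev[i]
    ta_amp <- 4 + 0.3 * lat[i]
    ta <- ta_mean + ta_amp * cos(2 * pi * (doy - 200) / 365) +
      ar1_series(n, 0.9, 0.58)

    # daytime VPD: log-linear in temperature plus independent synoptic
    # variation, so VPD and temperature effects remain separable
    vpd <- pmax(exp(log(400) + 0.065 * ta + ar1_series(n, 0.85, 0.12)), 1)

    co2 <- 380 + 2.2 * t_years + 3 * sin(2 * pi * (doy + 60) / 365) +
      stats::rnorm(n, 0, 1.5)

    # two-parameter bucket soil moisture: stochastic precipitation minus
    # radiation/temperature-driven evaporative draw-down
    capacity <- 150
    precip <- stats::rbinom(n, 1, 0.3) * stats::rexp(n, 1 / 6)
    pet <- pmax(0.05, 0.05 * (ta + 15)) * (sw_in / 150)
    store <- numeric(n)
    s <- 0.7 * capacity
    for (t in seq_len(n)) {
      s <- s + precip[t] - pet[t] * (s / capacity)
      s <- min(max(s, 0.5), capacity)
      store[t] <- s
    }
    soil_m <- store / capacity

    # canopy phenology: logistic green-up and senescence scaled by
    # latitude-dependent season length
    g_on <- 60 + 1.5 * (lat[i] - 30)
    g_off <- 305 - 1.2 * (lat[i] - 30)
    fmin <- 0.08
    fapar_true <- fmin + (fmax[i] - fmin) *
      (stats::plogis((doy - g_on) / 8) - stats::plogis((doy - g_off) / 10))
    fapar_true <- pmin(pmax(fapar_true, 0.02), 1)

    # sparse, noisy fAPAR observations with contamination and saturation
    obs_idx <- seq(1, n, by = cf$fapar_obs_interval_days)
    fapar_obs <- rep(NA_real_, n)
    fo <- fapar_true[obs_idx] *
      exp(stats::rnorm(length(obs_idx), 0, cf$fapar_noise_sd))
    u <- stats::runif(length(obs_idx))
    out_l <- u < cf$fapar_outlier_rate
    unity <- !out_l & u < cf$fapar_outlier_rate + cf$fapar_unity_rate
    fo[out_l] <- fo[out_l] * stats::runif(sum(out_l), 0.15, 0.4)
    fo[unity] <- 1.0
    fapar_obs[obs_idx] <- pmin(pmax(fo, 0.005), 1)

    # diffuse photon flux from the Bristow relation (umol m-2 s-1)
    t_t <- ifelse(sw_in_pot > 0, sw_in / sw_in_pot, NA_real_)
    s_d <- ifelse(is.na(t_t), 0,
                  diffuse_transmittance(pmax(t_t, 1e-6), cf$bristow_b) *
                    sw_in_pot)
    ppfd_dif <- if (has_dif[i]) s_d * 2.04 else rep(NA_real_, n)

    # ground-truth LUE from the generating fixed and random effects
    yrs <- sort(unique(year))
    a_year <- stats::rnorm(length(yrs), 0, cf$sd_year)
    a_year_day <- a_year[match(year, yrs)]
    tc <- ta - cf$temp_center
    eta <- beta["intercept"] + beta["temp"] * tc + beta["temp2"] * tc^2 +
      beta["log_vpd"] * log(vpd) + beta["log_soil_m"] * log(soil_m) +
      beta["log_ci"] * log(ci) + a_site[i] + a_year_day
    lue_true <- exp(as.numeric(eta))

    eps <- if (noise_free) rep(1, n) else
      stats::rgamma(n, shape = cf$gamma_shape, rate = cf$gamma_shape)
    # slowly varying residual LUE variation (the epsilon of the window-
    # scale model); persists within windows, unlike the daily gamma noise
    eps_proc <- if (cf$lue_process_sd > 0)
      exp(ar1_series(n, cf$lue_process_ar,
                     cf$lue_process_sd * sqrt(1 - cf$lue_process_ar^2)))
    else rep(1, n)
    ppfd_mol <- sw_in * 2.04e-6 * 86400
    gpp <- lue_true * fapar_true * ppfd_mol * eps * eps_proc * 12.011

    gapfill_frac <- gapfill_series(n, cf$gap_rate)

    # growing-season truth from the noise-free GPP series
    gpp_clean <- lue_true * fapar_true * ppfd_mol
    in_gs <- logical(n)
    for (y in yrs) {
      sel <- year == y
      m <- try(growing_season_mask(gpp_clean[sel]), silent = TRUE)
      in_gs[sel] <- if (inherits(m, "try-error")) FALSE else m
    }

    daily[[i]] <- data.frame(
      site_id = site_id[i], date = dates, gpp = gpp, sw_in = sw_in,
      sw_in_pot = sw_in_pot, ppfd_dif = ppfd_dif, ta_day = ta,
      vpd_day = vpd, co2 = co2, soil_m = soil_m, fapar_obs = fapar_obs,
      gapfill_frac = gapfill_frac, elevation = elev[i],
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      site_id = site_id[i], date = dates, lue_true = lue_true,
      fapar_true = fapar_true, site_intercept = a_site[i],
      year_intercept = a_year_day, in_growing_season = in_gs,
      stringsAsFactors = FALSE)
  }

  out <- list(daily = do.call(rbind, daily),
              truth = do.call(rbind, truth),
              sites = data.frame(site_id = site_id, latitude = lat,
                                 elevation = elev, has_diffuse = has_dif,
                                 stringsAsFactors = FALSE),
              config = cf)
  rownames(out$daily) <- NULL
  rownames(out$truth) <- NULL
  class(out) <- "lue_network"
  out
}

#' @export
print.lue_network <- function(x, ...) {
  cat(sprintf("Synthetic flux network: %d sites, %d daily records (%s to %s)\n",
              nrow(x$sites), nrow(x$daily),
              min(x$daily$date), max(x$daily$date)))
  invisible(x)
}
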