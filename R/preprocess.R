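#' Quality-filter and compositing thresholds
#'
#' Collects the tunable constants of the daily-to-composite pipeline.
#' Defaults follow common flux-data practice: days with half or more of
#' the underlying half-hourly data gap-filled are dropped, apparent
#' daily LUE above 0.12 mol C mol-1 photons is treated as infeasible,
#' near-zero absorbed light (absorbed PPFD below 0.1 mol m-2 d-1) is
#' excluded to avoid ratio blow-ups, the growing season is the part of
#' each site-year where GPP scaled to its 0.05--0.95 quantile range
#' exceeds 0.2, and composites are non-overlapping 15-day windows.
#'
#' @param max_gapfill_frac Days with `gapfill_frac >= max_gapfill_frac`
#'   are dropped (default 0.5, strict "less than half" reading).
#' @param max_lue Daily apparent LUE cap (mol C mol-1 photons).
#' @param min_absorbed_ppfd Minimum absorbed PPFD (mol m-2 d-1).
#' @param growing_season_quantiles Lower/upper quantiles of daily GPP
#'   used to scale each site-year.
#' @param growing_season_keep Scaled-GPP threshold above which a day
#'   counts as growing season.
#' @param window_days Length of the compositing window (days).
#' @param min_siteyear_days Minimum number of valid days for a
#'   site-year to enter the growing-season computation.
#' @param ci_aggregation Window cloudiness: `"ratio_of_sums"`
#'   (energy-consistent, `1 - sum(S_t)/sum(S_o)`) or `"mean_of_days"`.
#' @param fapar_source `"interpolate"` fits a smoothing spline through
#'   the sparse `fapar_obs` series per site; `"column"` uses
#'   `fapar_obs` directly as a daily value (it must then be complete).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_gapfill_frac = 0.5,
                              max_lue = 0.12,
                              min_absorbed_ppfd = 0.1,
                              growing_season_quantiles = c(0.05, 0.95),
                              growing_season_keep = 0.2,
                              window_days = 15L,
                              min_siteyear_days = 30L,
                              ci_aggregation = c("ratio_of_sums",
                                                 "mean_of_days"),
                              fapar_source = c("interpolate", "column")) {
  stopifnot(max_lue > 0,
            growing_season_quantiles[1] < growing_season_quantiles[2],
            growing_season_keep > 0, growing_season_keep < 1,
            window_days >= 1)
  th <- list(max_gapfill_frac = max_gapfill_frac,
             max_lue = max_lue,
             min_absorbed_ppfd = min_absorbed_ppfd,
             growing_season_quantiles = growing_season_quantiles,
             growing_season_keep = growing_season_keep,
             window_days = as.integer(window_days),
             min_siteyear_days = as.integer(min_siteyear_days),
             ci_aggregation = match.arg(ci_aggregation),
             fapar_source = match.arg(fapar_source))
  class(th) <- "filter_thresholds"
  th
}

# molar mass of carbon, g mol-1; converts GPP in gC to mol C
.MOLAR_MASS_C <- 12.011

#' Quality filters on daily site records
#'
#' Drops site-days with (i) a gap-filled fraction at or above the
#' threshold, (ii) negative GPP, (iii) near-zero absorbed light
#' (PPFD x fAPAR below `min_absorbed_ppfd`), or (iv) apparent daily
#' LUE above `max_lue`.
#'
#' @param records Daily data.frame with columns `gpp` (gC m-2 d-1),
#'   `gapfill_frac`, `ppfd` (mol m-2 d-1) and `fapar` (daily fraction).
#' @param thresholds A [filter_thresholds()] object.
#' @return List with `records` (the surviving rows) and `audit`, a
#'   named count of violations per rule (a row violating several rules
#'   counts once under each).
#' @export
filter_site_days <- function(records, thresholds = filter_thresholds()) {
  stopifnot(all(c("gpp", "gapfill_frac", "ppfd", "fapar") %in%
                  names(records)))
  absorbed <- records$ppfd * records$fapar
  lue_day <- ifelse(absorbed > 0,
                    (records$gpp / .MOLAR_MASS_C) / absorbed, Inf)
  bad_gap <- records$gapfill_frac >= thresholds$max_gapfill_frac
  bad_gpp <- records$gpp < 0
  bad_absorbed <- absorbed < thresholds$min_absorbed_ppfd
  bad_lue <- records$gpp >= 0 & lue_day > thresholds$max_lue
  drop <- bad_gap | bad_gpp | bad_absorbed | bad_lue
  list(records = records[!drop, , drop = FALSE],
       audit = c(gapfill = sum(bad_gap),
                 negative_gpp = sum(bad_gpp),
                 low_absorbed_light = sum(bad_absorbed),
                 lue_cap = sum(bad_lue),
                 dropped = sum(drop),
                 retained = sum(!drop)))
}

#' Growing-season mask for one site-year of daily GPP
#'
#' Scales the daily GPP of a site-year so its lower quantile maps to 0
#' and its upper quantile to 1 (defaults 0.05 and 0.95, quantiles by
#' linear interpolation of order statistics), then retains days whose
#' scaled GPP exceeds the keep threshold (default 0.2).
#'
#' @param gpp Numeric vector of daily GPP for one site-year.
#' @param quantiles Length-2 scaling quantiles.
#' @param keep Scaled threshold in (0, 1).
#' @return Logical vector, TRUE for growing-season days.  Errors when
#'   the two quantiles coincide (constant series: the site-year must be
#'   excluded).
#' @examples
#' growing_season_mask(0:99)  # retains values >= 23
#' @export
growing_season_mask <- function(gpp, quantiles = c(0.05, 0.95),
                                keep = 0.2) {
  q <- stats::quantile(gpp, quantiles, na.rm = TRUE, names = FALSE,
                       type = 7)
  if (!(q[2] > q[1]))
    stop("growing_season_mask: degenerate GPP series (q", quantiles[2],
         " = q", quantiles[1], ")")
  scaled <- (gpp - q[1]) / (q[2] - q[1])
  !is.na(scaled) & scaled > keep
}

#' Cut retained daily records into 15-day composite windows
#'
#' Within each site, maximal runs of consecutive retained days are cut
#' into non-overlapping windows of `window_days` days starting at each
#' run's first day; trailing stubs shorter than a full window are
#' discarded.  Per window, LUE is the ratio of accumulated GPP (mol C)
#' to accumulated PPFD times the window-mean fAPAR; the environmental
#' predictors are window means, except cloudiness which by default is
#' the energy-consistent ratio of sums `1 - sum(S_t)/sum(S_o)`.
#'
#' @param records Daily data.frame (already filtered and
#'   growing-season masked) with columns `site_id`, `date`, `gpp`,
#'   `ppfd`, `fapar`, `sw_in`, `sw_in_pot`, `ta_day`, `vpd_day`,
#'   `soil_m`, and optionally `ppfd_dif`, `co2`, `elevation`.
#' @param thresholds A [filter_thresholds()] object.
#' @return A data.frame of class `lue_composites`, one row per window,
#'   with columns `site_id`, `year`, `window_index`, `lue`, `temp`,
#'   `vpd`, `soil_m`, `ci`, `td`, `fapar`, `ppfd`, `co2`, `elevation`,
#'   `n_days`.  The day-to-window assignment is kept in
#'   `attr(, "membership")`.
#' @export
compose_windows <- function(records, thresholds = filter_thresholds()) {
  w <- thresholds$window_days
  empty <- function() {
    comp <- data.frame(site_id = character(), year = integer(),
                       window_index = integer(), lue = numeric(),
                       temp = numeric(), vpd = numeric(),
                       soil_m = numeric(), ci = numeric(),
                       td = numeric(), fapar = numeric(),
                       ppfd = numeric(), co2 = numeric(),
                       elevation = numeric(), n_days = integer())
    attr(comp, "membership") <- NULL
    class(comp) <- c("lue_composites", "data.frame")
    comp
  }
  if (nrow(records) == 0) return(empty())
  r <- records[order(records$site_id, records$date), , drop = FALSE]
  n <- nrow(r)
  new_run <- c(TRUE, r$site_id[-1] != r$site_id[-n] |
                 diff(as.numeric(r$date)) != 1)
  run <- cumsum(new_run)
  pos <- stats::ave(seq_len(n), run, FUN = seq_along)
  block <- (pos - 1) %/% w
  key <- run * 1e6 + block
  full <- stats::ave(key, key, FUN = length) == w
  r <- r[full, , drop = FALSE]
  if (nrow(r) == 0) return(empty())
  key <- key[full]
  kf <- factor(key, levels = unique(key))   # keeps site/date order

  msum <- function(v) as.numeric(rowsum(v, kf, reorder = FALSE))
  first <- !duplicated(kf)
  if (is.null(r$co2)) r$co2 <- NA_real_
  if (is.null(r$elevation)) r$elevation <- NA_real_
  if (is.null(r$ppfd_dif)) r$ppfd_dif <- NA_real_

  sum_sw <- msum(r$sw_in); sum_pot <- msum(r$sw_in_pot)
  ci <- if (thresholds$ci_aggregation == "ratio_of_sums")
    1 - sum_sw / sum_pot
  else msum(cloudiness_index(r$sw_in, r$sw_in_pot)) / w
  td_ok <- as.logical(msum(as.numeric(is.finite(r$ppfd_dif))) == w)
  td <- ifelse(td_ok,
               msum(ifelse(is.finite(r$ppfd_dif), r$ppfd_dif, 0) / 2.04) /
                 sum_pot,
               NA_real_)

  comp <- data.frame(
    site_id = r$site_id[first],
    year = as.integer(format(r$date[first], "%Y")),
    window_index = NA_integer_,
    lue = (msum(r$gpp) / .MOLAR_MASS_C) /
      (msum(r$ppfd) * (msum(r$fapar) / w)),
    temp = msum(r$ta_day) / w,
    vpd = msum(r$vpd_day) / w,
    soil_m = msum(r$soil_m) / w,
    ci = ci,
    td = td,
    fapar = msum(r$fapar) / w,
    ppfd = msum(r$ppfd) / w,
    co2 = msum(r$co2) / w,
    elevation = r$elevation[first],
    n_days = w,
    stringsAsFactors = FALSE)
  comp$window_index <- stats::ave(seq_len(nrow(comp)), comp$site_id,
                                  FUN = seq_along)
  rownames(comp) <- NULL
  attr(comp, "membership") <- data.frame(
    site_id = r$site_id, date = r$date,
    window_index = comp$window_index[as.integer(kf)],
    stringsAsFactors = FALSE)
  class(comp) <- c("lue_composites", "data.frame")
  comp
}

#' Run the full daily-to-composite preprocessing pipeline
#'
#' Converts a table of daily site records into growing-season 15-day
#' composite records carrying LUE and averaged predictors.  Stages:
#' photon-flux conversion, cloudiness index, Bristow gap-filling of the
#' diffuse stream (fitting `B` from days with observed diffuse radiation
#' unless `bristow_b` is supplied), per-site fAPAR interpolation,
#' quality filters, per-site-year growing-season masking, and window
#' compositing.
#'
#' @param daily Daily data.frame in the layout produced by
#'   [generate_site_network()] or [read_daily_table()].
#' @param thresholds A [filter_thresholds()] object.
#' @param bristow_b Optional fixed Bristow coefficient; if `NULL` it is
#'   fitted from the data's observed diffuse radiation (falling back to
#'   0.889 with a message when no site reports diffuse radiation).
#' @param gs_flags Optional externally supplied growing-season
#'   classification (data.frame with `site_id`, `date` and a logical
#'   `in_growing_season`), e.g. from independent phenology or the
#'   synthetic generator's ground truth.  When given it replaces the
#'   GPP-quantile growing-season estimate.
#' @return An `lue_composites` data.frame (see [compose_windows()])
#'   with attributes `audit` (named exclusion counts), `bristow`
#'   (the [fit_bristow()] result or the fixed coefficient) and
#'   `thresholds`.
#' @examples
#' net <- generate_site_network(synth_config(n_sites = 2, seed = 7))
#' comp <- make_composites(net$daily)
#' head(comp)
#' attr(comp, "audit")
#' @export
make_composites <- function(daily, thresholds = filter_thresholds(),
                            bristow_b = NULL, gs_flags = NULL) {
  need <- c("site_id", "date", "gpp", "sw_in", "sw_in_pot", "ta_day",
            "vpd_day", "soil_m", "fapar_obs", "gapfill_frac")
  miss <- setdiff(need, names(daily))
  if (length(miss))
    stop("make_composites: missing columns: ", paste(miss, collapse = ", "))
  if (is.null(daily$ppfd_dif)) daily$ppfd_dif <- NA_real_

  audit <- c(no_radiation = 0, fapar_site_excluded = 0,
             gs_siteyear_excluded = 0, non_growing_season = 0)

  ok_rad <- is.finite(daily$sw_in_pot) & daily$sw_in_pot > 0 &
    is.finite(daily$sw_in) & daily$sw_in >= 0
  audit["no_radiation"] <- sum(!ok_rad)
  daily <- daily[ok_rad, , drop = FALSE]
  daily$ppfd <- ppfd_from_shortwave(daily$sw_in)

  # Bristow coefficient: fit from observed diffuse radiation if possible
  bristow <- NULL
  if (is.null(bristow_b)) {
    obs <- is.finite(daily$ppfd_dif) & daily$sw_in > 0
    if (sum(obs) >= 10) {
      t_t <- daily$sw_in[obs] / daily$sw_in_pot[obs]
      t_d <- (daily$ppfd_dif[obs] / 2.04) / daily$sw_in_pot[obs]
      bristow <- fit_bristow(t_d, t_t)
      bristow_b <- bristow$B
    } else {
      message("make_composites: no observed diffuse radiation; ",
              "using default Bristow B = 0.889")
      bristow_b <- 0.889
    }
  }
  daily <- gapfill_diffuse(daily, bristow_b)

  # daily fAPAR per site
  daily$fapar <- NA_real_
  if (thresholds$fapar_source == "column") {
    if (any(!is.finite(daily$fapar_obs)))
      stop("fapar_source = 'column' requires a complete daily fapar_obs")
    daily$fapar <- daily$fapar_obs
  } else {
    keep_sites <- character()
    for (sid in unique(daily$site_id)) {
      sel <- daily$site_id == sid
      fa <- try(interpolate_fapar(daily$date[sel], daily$fapar_obs[sel],
                                  daily$date[sel]), silent = TRUE)
      if (inherits(fa, "try-error")) {
        audit["fapar_site_excluded"] <- audit["fapar_site_excluded"] + 1
      } else {
        daily$fapar[sel] <- fa
        keep_sites <- c(keep_sites, sid)
      }
    }
    daily <- daily[daily$site_id %in% keep_sites, , drop = FALSE]
  }

  flt <- filter_site_days(daily, thresholds)
  audit <- c(audit, flt$audit)
  daily <- flt$records

  # growing season per site-year on the quality-filtered days
  yr <- as.integer(format(daily$date, "%Y"))
  sy <- paste(daily$site_id, yr)
  keep <- logical(nrow(daily))
  in_valid_sy <- logical(nrow(daily))
  if (!is.null(gs_flags)) {
    stopifnot(all(c("site_id", "date", "in_growing_season") %in%
                    names(gs_flags)))
    idx <- match(paste(daily$site_id, daily$date),
                 paste(gs_flags$site_id, gs_flags$date))
    keep <- !is.na(idx) & gs_flags$in_growing_season[idx]
    in_valid_sy <- !is.na(idx)
  } else for (key in unique(sy)) {
    sel <- sy == key
    if (sum(sel) < thresholds$min_siteyear_days) {
      audit["gs_siteyear_excluded"] <- audit["gs_siteyear_excluded"] + 1
      next
    }
    m <- try(growing_season_mask(daily$gpp[sel],
                                 thresholds$growing_season_quantiles,
                                 thresholds$growing_season_keep),
             silent = TRUE)
    if (inherits(m, "try-error")) {
      audit["gs_siteyear_excluded"] <- audit["gs_siteyear_excluded"] + 1
      next
    }
    in_valid_sy[sel] <- TRUE
    keep[sel] <- m
  }
  audit["non_growing_season"] <- sum(in_valid_sy & !keep)
  daily <- daily[keep, , drop = FALSE]

  comp <- compose_windows(daily, thresholds)
  audit["windows"] <- nrow(comp)
  attr(comp, "audit") <- audit
  attr(comp, "bristow") <- if (is.null(bristow)) bristow_b else bristow
  attr(comp, "thresholds") <- thresholds
  comp
}

#' @export
print.lue_composites <- function(x, ...) {
  cat(sprintf("LUE composites: %d windows, %d site(s), years %s-%s\n",
              nrow(x), length(unique(x$site_id)),
              if (nrow(x)) min(x$year) else NA,
              if (nrow(x)) max(x$year) else NA))
  if (nrow(x)) {
    cat(sprintf("  LUE (mol C mol-1 photons): median %.4f, range %.4f-%.4f\n",
                stats::median(x$lue), min(x$lue), max(x$lue)))
    print(utils::head(as.data.frame(x), 6))
    if (nrow(x) > 6) cat(sprintf("  ... %d more window(s)\n", nrow(x) - 6))
  }
  invisible(x)
}
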