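# FLUXNET-style CSV dialect: internal name <-> column name
.daily_cols <- c(site_id = "SITE_ID", date = "DATE",
                 gpp = "GPP_NT_VUT_REF", sw_in = "SW_IN_F",
                 sw_in_pot = "SW_IN_POT", ppfd_dif = "PPFD_DIF",
                 ta_day = "TA_F_DAY", vpd_day = "VPD_F",
                 co2 = "CO2_F_MDS", soil_m = "SOIL_M",
                 fapar_obs = "FAPAR_OBS", gapfill_frac = "GAPFILL_FRAC",
                 elevation = "ELEV")
.required_cols <- c("SITE_ID", "DATE", "GPP_NT_VUT_REF", "SW_IN_F",
                    "SW_IN_POT", "TA_F_DAY", "VPD_F")

#' Read a daily site table in the FLUXNET-style CSV dialect
#'
#' Reads columns `SITE_ID`, `DATE` (ISO-8601), `GPP_NT_VUT_REF`,
#' `SW_IN_F`, `SW_IN_POT`, `PPFD_DIF`, `TA_F_DAY`, `VPD_F`,
#' `CO2_F_MDS`, `SOIL_M`, `FAPAR_OBS`, `GAPFILL_FRAC`, `ELEV` into the
#' internal layout used by [make_composites()].  The FLUXNET missing
#' sentinel -9999 is mapped to `NA`; unknown columns are preserved
#' untouched.
#'
#' @param path CSV file path (lines starting with `#` are ignored).
#' @return Daily data.frame with internal column names.
#' @export
read_daily_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(.required_cols, names(d))
  if (length(miss))
    stop("daily table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(d) == 0) warning("empty daily table: ", path)
  for (v in names(d))
    if (is.numeric(d[[v]])) d[[v]][d[[v]] == -9999] <- NA
  idx <- match(.daily_cols, names(d))
  out <- d
  names(out)[idx[!is.na(idx)]] <- names(.daily_cols)[!is.na(idx)]
  if (nrow(out)) out$date <- as.Date(out$date)
  for (v in setdiff(names(.daily_cols),
                    c("site_id", "date", names(out)[idx[!is.na(idx)]])))
    if (is.null(out[[v]])) out[[v]] <- rep(NA_real_, nrow(out))
  out
}

#' Write a daily site table in the FLUXNET-style CSV dialect
#'
#' Inverse of [read_daily_table()]: internal names are mapped to the
#' FLUXNET-style headers, missing values to -9999, dates to ISO-8601.
#'
#' @param daily Daily data.frame with internal column names.
#' @param path Output CSV path.
#' @param comment Optional comment line(s) written before the header,
#'   each prefixed with `#`.
#' @return `path`, invisibly.
#' @export
write_daily_table <- function(daily, path, comment = NULL) {
  d <- daily
  idx <- match(names(.daily_cols), names(d))
  names(d)[idx[!is.na(idx)]] <- .daily_cols[!is.na(idx)]
  d$DATE <- format(as.Date(d$DATE), "%Y-%m-%d")
  for (v in names(d))
    if (is.numeric(d[[v]])) d[[v]][!is.finite(d[[v]])] <- -9999
  .write_csv(d, path, comment)
  invisible(path)
}

.write_csv <- function(d, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Everything one end-to-end run needs: the input (a daily CSV or a
#' [synth_config()] to simulate one), the thresholds, the candidate
#' design ladder, the simulator parameters, optional third-party model
#' output, and the seed.  The MD5 hash of the configuration is stamped
#' into every output file, so reruns with altered settings are
#' distinguishable.
#'
#' @param out_dir Output directory (created if absent).
#' @param daily_csv Path to an input daily CSV; if `NULL`, data are
#'   simulated from `synth`.
#' @param synth A [synth_config()] used when `daily_csv` is `NULL`.
#' @param thresholds A [filter_thresholds()].
#' @param ladder Candidate designs, as [default_ladder()].
#' @param pmodel A [pmodel_params()].
#' @param model_output_csv Optional CSV of third-party model output with
#'   columns `MODEL`, `SITE_ID`, `DATE`, `GPP`, and `LAI` or `FAPAR`.
#' @param response_variables Variables for the response-curve stage.
#' @param seed Integer seed for the whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, daily_csv = NULL, synth = synth_config(),
                       thresholds = filter_thresholds(),
                       ladder = default_ladder(),
                       pmodel = pmodel_params(),
                       model_output_csv = NULL,
                       response_variables = c("temp", "vpd", "soil_m",
                                              "ci"),
                       seed = 1L) {
  cfg <- list(out_dir = out_dir, daily_csv = daily_csv, synth = synth,
              thresholds = thresholds, ladder = ladder, pmodel = pmodel,
              model_output_csv = model_output_csv,
              response_variables = response_variables,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

#' Run the end-to-end LUE analysis pipeline
#'
#' Executes simulate (when no input CSV is given), preprocess, model
#' selection, conditional response curves, the optimality-model
#' overlay, and (when model output is supplied) the ensemble
#' comparison, writing all artifacts to `config$out_dir`:
#' `daily.csv`/`truth.csv` (simulated input), `composites.csv`,
#' `filter_audit.json`, `selection.csv`, `fit_best.json`,
#' `response_curves.csv`, `pmodel_curves.csv`, `ensemble_curves.csv`
#' and `nse.json` (with model output), `provenance.json` and `run.log`.
#' Every file carries the configuration hash.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the main in-memory results
#'   (`composites`, `ladder`, `fit`, `curves`, `pmodel_curves`,
#'   `ensemble`, `cv`, `paths`, `hash`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  stamp <- paste0("config_hash: ", hash)
  logf <- file.path(config$out_dir, "run.log")
  loglines <- c(paste("lueflux pipeline,", stamp),
                paste("seed:", config$seed))
  say <- function(...) loglines <<- c(loglines, paste0(...))
  paths <- character()
  add_path <- function(p) paths <<- c(paths, p)
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      say("STAGE FAILED [", name, "]: ", conditionMessage(e))
      writeLines(loglines, logf)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say("stage ", name, ": ok")
    out
  }

  set.seed(config$seed)

  daily <- stage("simulate", {
    if (is.null(config$daily_csv)) {
      net <- generate_site_network(config$synth)
      write_daily_table(net$daily,
                        file.path(config$out_dir, "daily.csv"), stamp)
      .write_csv(net$truth, file.path(config$out_dir, "truth.csv"),
                 stamp)
      add_path(file.path(config$out_dir, c("daily.csv", "truth.csv")))
      net$daily
    } else read_daily_table(config$daily_csv)
  })

  comp <- stage("preprocess", {
    comp <- make_composites(daily, config$thresholds)
    .write_csv(as.data.frame(comp),
               file.path(config$out_dir, "composites.csv"), stamp)
    audit <- as.list(attr(comp, "audit"))
    audit$config_hash <- hash
    audit$seed <- config$seed
    br <- attr(comp, "bristow")
    audit$bristow_b <- if (inherits(br, "bristow_fit")) br$B else br
    jsonlite::write_json(audit,
                         file.path(config$out_dir, "filter_audit.json"),
                         auto_unbox = TRUE, digits = NA)
    add_path(file.path(config$out_dir,
                       c("composites.csv", "filter_audit.json")))
    comp
  })

  sel <- stage("select", {
    sel <- selection_ladder(comp, config$ladder)
    .write_csv(as.data.frame(sel),
               file.path(config$out_dir, "selection.csv"), stamp)
    add_path(file.path(config$out_dir, "selection.csv"))
    sel
  })
  fits <- attr(sel, "fits")
  best <- fits[[which(sel$best)[1]]]
  say("preferred design: ", sel$model[sel$best][1])

  cv <- stage("cross_validate", loo_site_cv(comp, best$design,
                                            temp_center = best$temp_center))

  stage("fit_summary", {
    fs <- list(config_hash = hash, seed = config$seed,
               design = best$design$label,
               fixed_terms = best$design$fixed,
               coefficients = as.list(best$beta),
               standard_errors = as.list(best$beta_se),
               sigma2_site = best$sigma2_site,
               sigma2_year = best$sigma2_year,
               shape = best$shape, loglik = best$loglik, df = best$df,
               aic = best$aic, bic = best$bic, n = best$n,
               temp_center = best$temp_center,
               converged = best$converged,
               variance_partition = as.list(variance_partition(best)),
               temperature_optimum = unclass(temperature_optimum(best)),
               r2_cv = cv$r2_cv, r2_fixed = cv$r2_fixed)
    jsonlite::write_json(fs, file.path(config$out_dir, "fit_best.json"),
                         auto_unbox = TRUE, digits = NA)
    add_path(file.path(config$out_dir, "fit_best.json"))
    fs
  })

  curves <- stage("respond", {
    in_design <- unique(unlist(lapply(.term_registry[best$design$fixed],
                                      `[[`, "raw")))
    vars <- intersect(config$response_variables, in_design)
    cl <- lapply(vars, function(v) conditional_response(best, v))
    names(cl) <- vars
    .write_csv(do.call(rbind, lapply(cl, as.data.frame)),
               file.path(config$out_dir, "response_curves.csv"), stamp)
    add_path(file.path(config$out_dir, "response_curves.csv"))
    cl
  })

  pcurves <- stage("pmodel", {
    vars <- intersect(config$response_variables,
                      c("temp", "vpd", "soil_m", "ci", "co2",
                        "elevation"))
    pl <- lapply(vars, function(v)
      stylized_experiment(comp, v, params = config$pmodel))
    names(pl) <- vars
    .write_csv(do.call(rbind, lapply(pl, as.data.frame)),
               file.path(config$out_dir, "pmodel_curves.csv"), stamp)
    add_path(file.path(config$out_dir, "pmodel_curves.csv"))
    pl
  })

  ensemble <- NULL
  if (!is.null(config$model_output_csv)) {
    ensemble <- stage("compare", {
      mo <- utils::read.csv(config$model_output_csv,
                            stringsAsFactors = FALSE, comment.char = "#")
      names(mo) <- tolower(names(mo))
      names(mo)[names(mo) == "gpp"] <- "gpp_sim"
      names(mo)[names(mo) == "lai"] <- "lai_sim"
      names(mo)[names(mo) == "fapar"] <- "fapar_sim"
      mo$date <- as.Date(mo$date)
      mc <- model_lue_composites(mo, daily, config$thresholds,
                                 composites = comp)
      ens <- ensemble_fit(mc, best$design,
                          variables = config$response_variables,
                          temp_center = best$temp_center)
      crv <- do.call(rbind, unlist(lapply(names(ens), function(m)
        lapply(ens[[m]]$curves, function(cc) {
          cc <- as.data.frame(cc); cc$model <- m; cc
        })), recursive = FALSE))
      if (!is.null(crv))
        .write_csv(crv, file.path(config$out_dir, "ensemble_curves.csv"),
                   stamp)
      nse <- lapply(mc, function(d)
        nash_sutcliffe(d$gpp_obs, d$gpp_sim))
      jsonlite::write_json(
        list(config_hash = hash, nse_gpp = nse,
             converged = lapply(ens, `[[`, "converged")),
        file.path(config$out_dir, "nse.json"), auto_unbox = TRUE,
        digits = NA)
      add_path(file.path(config$out_dir,
                         c("ensemble_curves.csv", "nse.json")))
      ens
    })
  }

  stage("provenance", {
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           package_version = as.character(utils::packageVersion("lueflux")),
           r_version = R.version.string,
           n_windows = nrow(comp),
           stages = c("simulate", "preprocess", "select",
                      "cross_validate", "respond", "pmodel",
                      if (!is.null(ensemble)) "compare")),
      file.path(config$out_dir, "provenance.json"), auto_unbox = TRUE,
      digits = NA)
    add_path(file.path(config$out_dir, "provenance.json"))
    NULL
  })

  writeLines(loglines, logf)
  add_path(logf)
  invisible(list(composites = comp, ladder = sel, fit = best,
                 curves = curves, pmodel_curves = pcurves,
                 ensemble = ensemble, cv = cv, paths = paths,
                 hash = hash))
}
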