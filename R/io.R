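#' Canonical station-table column schema
#'
#' Ordered column names of the station CSV exchanged by the package:
#' station id, the five constituent drivers (units embedded in the
#' names), then per band the measured IOPs (m-1), radiometry (relative
#' energy units) and reflectance (sr-1).
#'
#' @return Character vector of column names.
#' @export
station_schema <- function() {
  c("station_id", "chl_a_mg_m3", "sum_c_mg_m3", "spm_g_m3",
    "spm_inorg_g_m3", "a_cdom_400_m1",
    unlist(lapply(rrs_bands(), function(b)
      paste0(c("aph_", "ad_", "acdom_", "bbp_", "lu_", "ed_", "eu_",
               "rrs_"), b))))
}

#' Read a station table from CSV
#'
#' Reads and validates a station CSV against [station_schema()]: the
#' header must contain at least the constituent columns (extra columns
#' beyond the schema are rejected, missing measurement columns are
#' allowed), numbers must parse, and physically impossible rows
#' (negative concentrations, inorganic SPM above total, pigments without
#' chlorophyll) are rejected with row-numbered messages.
#'
#' @param path CSV file path.
#' @return Validated station data frame.
#' @export
read_station_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse station CSV: ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tbl) == 0L || ncol(tbl) <= 1L) {
    stop("station CSV is empty or has no columns", call. = FALSE)
  }
  const_cols <- c("station_id", "chl_a_mg_m3", "sum_c_mg_m3", "spm_g_m3",
                  "spm_inorg_g_m3", "a_cdom_400_m1")
  miss <- setdiff(const_cols, names(tbl))
  if (length(miss) > 0L) {
    stop("station CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(tbl), station_schema())
  if (length(unknown) > 0L) {
    stop("station CSV has unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(names(tbl), "station_id")
  for (nm in num_cols) {
    if (!is.numeric(tbl[[nm]])) {
      stop(sprintf("column `%s` contains non-numeric values", nm),
           call. = FALSE)
    }
  }
  bad <- which(!is.na(tbl$spm_inorg_g_m3) & !is.na(tbl$spm_g_m3) &
                 tbl$spm_inorg_g_m3 > tbl$spm_g_m3)
  if (length(bad) > 0L) {
    stop("spm_inorg_g_m3 > spm_g_m3 in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(tbl$sum_c_mg_m3) & !is.na(tbl$chl_a_mg_m3) &
                 tbl$sum_c_mg_m3 > 0 & tbl$chl_a_mg_m3 == 0)
  if (length(bad) > 0L) {
    stop("sum_c_mg_m3 > 0 with chl_a_mg_m3 = 0 in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in num_cols) {
    bad <- which(!is.na(tbl[[nm]]) & tbl[[nm]] < 0)
    if (length(bad) > 0L) {
      stop(sprintf("negative `%s` in row(s): %s", nm,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  tbl
}

#' Write a station table to CSV
#'
#' @param stations Station data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(stations, path) {
  utils::write.csv(stations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predict four-band reflectance for a constituent table
#'
#' @param stations Data frame with the five constituent columns.
#' @param coeffs Coefficient set.
#' @return Data frame with `station_id` (if present) and `rrs_<band>`
#'   predictions (sr-1).
#' @export
predict_rrs <- function(stations, coeffs = default_coefficients()) {
  cv <- station_constituents(stations)
  out <- data.frame(
    station_id = if ("station_id" %in% names(stations))
      stations$station_id else sprintf("S%04d", seq_len(nrow(stations)))
  )
  for (band in rrs_bands()) {
    out[[paste0("rrs_", band)]] <- rrs_forward(cv, band, coeffs)
  }
  out
}

#' Run one pipeline stage
#'
#' Programmatic equivalent of the command-line interface; each command
#' reads/writes CSV and JSON artifacts in `out_dir`:
#'
#' * `simulate`: write a synthetic station CSV (`stations.csv`);
#' * `calibrate`: fit all coefficients from a station CSV, writing
#'   `coefficients.json` and a plain-text `calibration_report.txt`;
#' * `predict`: write four-band reflectance predictions
#'   (`predictions.csv`) for the constituents of a station CSV;
#' * `evaluate`: write per-band error tables (`errors_<quantity>.csv`)
#'   comparing model predictions against measured columns.
#'
#' @param command One of `"simulate"`, `"calibrate"`, `"predict"`,
#'   `"evaluate"`.
#' @param stations_csv Input station CSV (all commands except
#'   `simulate`).
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed (`simulate`).
#' @param n Stations to simulate.
#' @param coeffs_json Optional coefficient JSON overriding the shipped
#'   set (`predict`, `evaluate`).
#' @param method Calibration method (see [calibrate_all()]).
#' @return Invisible list of written file paths.
#' @export
run_pipeline <- function(command = c("simulate", "calibrate", "predict",
                                     "evaluate"),
                         stations_csv = NULL, out_dir = ".", seed = 1L,
                         n = 200L, coeffs_json = NULL,
                         method = "two_step") {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  coeffs <- if (is.null(coeffs_json)) default_coefficients()
            else read_coefficients(coeffs_json)
  written <- list()
  if (command == "simulate") {
    tbl <- generate_dataset(population_params(n = n), coeffs, seed = seed)
    written$stations <- file.path(out_dir, "stations.csv")
    write_station_csv(tbl, written$stations)
  } else {
    if (is.null(stations_csv)) {
      stop("`stations_csv` is required for command ", command,
           call. = FALSE)
    }
    tbl <- read_station_csv(stations_csv)
    if (command == "calibrate") {
      res <- calibrate_all(tbl, method = method, reference = coeffs)
      written$coefficients <- file.path(out_dir, "coefficients.json")
      write_coefficients(res$coefficients, written$coefficients)
      written$report <- file.path(out_dir, "calibration_report.txt")
      writeLines(c(
        sprintf("calibration method: %s", res$method),
        sprintf("stations: %d", res$n_stations),
        sprintf("f/Q statistic: %s", res$f_over_q_stat),
        sprintf("covariate exclusions: pigment ratio %d, inorganic fraction %d",
                res$diagnostics$covariate_excluded[["aph"]],
                res$diagnostics$covariate_excluded[["particles"]]),
        sprintf("f/Q per band: %s",
                paste(sprintf("%d nm %.4f", rrs_bands(), res$f_over_q),
                      collapse = ", "))
      ), written$report)
    } else if (command == "predict") {
      written$predictions <- file.path(out_dir, "predictions.csv")
      utils::write.csv(predict_rrs(tbl, coeffs), written$predictions,
                       row.names = FALSE, quote = FALSE)
    } else {
      for (q in c("a_ph", "a_d", "a_cdom", "b_bp", "r_rs")) {
        tab <- build_error_table(tbl, coeffs, quantity = q)
        f <- file.path(out_dir, paste0("errors_", gsub("_", "", q), ".csv"))
        utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
        written[[paste0("errors_", q)]] <- f
      }
    }
  }
  invisible(written)
}
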