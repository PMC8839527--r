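#' Arithmetic and logarithmic error statistics
#'
#' The error framework used throughout the package compares calculated
#' (model) values against measured ones with two families of statistics:
#'
#' * arithmetic: per-point relative errors eps_i = (cal - meas)/meas,
#'   summarised by the relative mean (systematic) error <eps> and its
#'   population standard deviation sigma_eps (statistical error);
#' * logarithmic: based on log10(cal/meas), summarised by the mean
#'   logarithmic (systematic) error <eps>_g = 10^mean(log ratio) - 1, the
#'   standard error factor x = 10^sd(log ratio), and the asymmetric
#'   bounds sigma+ = x - 1 and sigma- = 1/x - 1.
#'
#' Logarithmic statistics suit quantities that vary over orders of
#' magnitude with multiplicative errors, which is the regime of coastal
#' IOPs. Standard deviations use the population (1/N) form.
#'
#' @name errstats
NULL

#' @rdname errstats
#' @param measured Strictly positive measured values.
#' @param calculated Model values, same length.
#' @return `pointwise_relative_errors()`: vector of eps_i (fractions).
#' @export
pointwise_relative_errors <- function(measured, calculated) {
  stopifnot(length(measured) == length(calculated))
  if (any(!is.finite(measured)) || any(measured <= 0)) {
    stop("`measured` must be strictly positive", call. = FALSE)
  }
  (calculated - measured) / measured
}

# population (1/N) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' @rdname errstats
#' @param eps Vector of relative errors (fractions), non-empty.
#' @param sample_sd Use the 1/(N-1) denominator instead of 1/N.
#' @return `arithmetic_summary()`: list with `eps_mean` and `sigma_eps`,
#'   both in percent.
#' @export
arithmetic_summary <- function(eps, sample_sd = FALSE) {
  if (length(eps) == 0L) stop("`eps` must be non-empty", call. = FALSE)
  s <- if (sample_sd && length(eps) > 1L) stats::sd(eps) else sd_pop(eps)
  list(eps_mean = 100 * mean(eps), sigma_eps = 100 * s)
}

#' @rdname errstats
#' @return `logarithmic_summary()`: list with `eps_g` (%), `sigma_log`
#'   (decades), `x_factor` (unitless, >= 1), `sigma_plus` (%) and
#'   `sigma_minus` (%).
#' @export
logarithmic_summary <- function(measured, calculated, sample_sd = FALSE) {
  stopifnot(length(measured) == length(calculated))
  if (length(measured) == 0L) stop("empty input", call. = FALSE)
  if (any(!is.finite(measured)) || any(measured <= 0) ||
      any(!is.finite(calculated)) || any(calculated <= 0)) {
    stop("log statistics require strictly positive values", call. = FALSE)
  }
  lr <- log10(calculated / measured)
  s <- if (sample_sd && length(lr) > 1L) stats::sd(lr) else sd_pop(lr)
  x <- 10^s
  list(
    eps_g = 100 * (10^mean(lr) - 1),
    sigma_log = s,
    x_factor = x,
    sigma_plus = 100 * (x - 1),
    sigma_minus = 100 * (1 / x - 1)
  )
}

#' Full error report for one model/band
#'
#' Combines both summaries into one row: <eps>, sigma_eps, <eps>_g, x,
#' sigma+, sigma- (all percentages except x and sigma_log) plus the
#' number of pairs used and the number dropped because the measured value
#' was not strictly positive.
#'
#' @inheritParams errstats
#' @param sample_sd Use 1/(N-1) denominators (off by default).
#' @return One-row data frame.
#' @export
error_report <- function(measured, calculated, sample_sd = FALSE) {
  stopifnot(length(measured) == length(calculated))
  keep <- is.finite(measured) & measured > 0 &
    is.finite(calculated) & calculated > 0
  dropped <- sum(!keep)
  m <- measured[keep]
  k <- calculated[keep]
  if (length(m) == 0L) stop("no usable (positive) pairs", call. = FALSE)
  ar <- arithmetic_summary(pointwise_relative_errors(m, k), sample_sd)
  lg <- logarithmic_summary(m, k, sample_sd)
  data.frame(
    eps_mean = ar$eps_mean, sigma_eps = ar$sigma_eps,
    eps_g = lg$eps_g, sigma_log = lg$sigma_log, x_factor = lg$x_factor,
    sigma_plus = lg$sigma_plus, sigma_minus = lg$sigma_minus,
    n = length(m), n_dropped = dropped
  )
}

#' Per-band error table for a component model or the reflectance model
#'
#' Computes model predictions for every station and band and summarises
#' prediction errors against the measured columns of a station table, in
#' the standard layout: systematic error, statistical error, systematic
#' log error, standard error factor, sigma+, sigma-.
#'
#' @param stations A station table (see [read_station_csv()] /
#'   [generate_dataset()]).
#' @param coeffs An [rrs_coefficients] set used for predictions.
#' @param quantity One of `"a_ph"`, `"a_d"`, `"a_cdom"`, `"b_bp"`,
#'   `"r_rs"`.
#' @param mode `"one_param"`, `"two_param"` or `"five_param"` (`"r_rs"`
#'   requires `"five_param"`; `"a_cdom"` has a single one-parameter
#'   model).
#' @param sample_sd Use 1/(N-1) denominators.
#' @return Data frame with one row per band, columns `band`, `quantity`,
#'   `mode` and the [error_report()] columns.
#' @export
build_error_table <- function(stations, coeffs = default_coefficients(),
                              quantity = c("a_ph", "a_d", "a_cdom",
                                           "b_bp", "r_rs"),
                              mode = c("two_param", "one_param",
                                       "five_param"),
                              sample_sd = FALSE) {
  quantity <- match.arg(quantity)
  mode <- match.arg(mode)
  if (quantity == "r_rs") mode <- "five_param"
  if (quantity == "a_cdom") mode <- "one_param"
  meas_prefix <- c(a_ph = "aph", a_d = "ad", a_cdom = "acdom",
                   b_bp = "bbp", r_rs = "rrs")[[quantity]]
  rows <- lapply(rrs_bands(), function(band) {
    mcol <- paste0(meas_prefix, "_", band)
    if (!mcol %in% names(stations)) {
      stop(sprintf("station table has no measured column `%s`", mcol),
           call. = FALSE)
    }
    pred <- switch(
      quantity,
      a_ph = if (mode == "one_param") aph_one_param(stations$chl_a_mg_m3, band)
             else aph_two_param(stations$chl_a_mg_m3, stations$sum_c_mg_m3,
                                band, coeffs),
      a_d = if (mode == "one_param") ad_one_param(stations$spm_g_m3, band)
            else ad_two_param(stations$spm_g_m3, stations$spm_inorg_g_m3,
                              band, coeffs),
      b_bp = if (mode == "one_param") bbp_one_param(stations$spm_g_m3, band)
             else bbp_two_param(stations$spm_g_m3, stations$spm_inorg_g_m3,
                                band, coeffs),
      a_cdom = acdom_model(stations$a_cdom_400_m1, band, coeffs),
      r_rs = rrs_forward(station_constituents(stations), band, coeffs)
    )
    cbind(data.frame(band = band, quantity = quantity, mode = mode),
          error_report(stations[[mcol]], pred, sample_sd))
  })
  do.call(rbind, rows)
}

# pull the five driver columns out of a station table
station_constituents <- function(stations) {
  constituents(
    chl_a = stations$chl_a_mg_m3,
    sum_c = stations$sum_c_mg_m3,
    spm = stations$spm_g_m3,
    spm_inorg = stations$spm_inorg_g_m3,
    a_cdom_400 = stations$a_cdom_400_m1
  )
}
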