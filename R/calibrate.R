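# coefficient of determination without summary.lm (which warns on exact fits)
r_squared <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / tss
}

#' Fit a power law by least squares in log-log space
#'
#' Fits y = coefficient * x^exponent by ordinary least squares of
#' log10(y) on log10(x). Pairs where either value is missing or not
#' strictly positive are dropped and counted; log-space fitting is the
#' standard choice for bio-optical quantities whose scatter is
#' multiplicative and which span orders of magnitude.
#'
#' @param x Driver values (> 0 after filtering).
#' @param y Response values (> 0 after filtering).
#' @return List of class `power_law_fit`: `coefficient`, `exponent`,
#'   `n_used`, `n_dropped`, `r_squared_log`.
#' @export
#' @examples
#' x <- 10^seq(-1, 2, length.out = 20)
#' fit_power_law(x, 0.056 * x^0.827)
fit_power_law <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(keep) < 2L) {
    stop("fit_power_law needs at least 2 strictly positive pairs",
         call. = FALSE)
  }
  lx <- log10(x[keep]); ly <- log10(y[keep])
  fit <- stats::lm(ly ~ lx)
  structure(list(
    coefficient = 10^unname(stats::coef(fit)[1]),
    exponent = unname(stats::coef(fit)[2]),
    n_used = sum(keep),
    n_dropped = sum(!keep),
    r_squared_log = r_squared(fit, ly)
  ), class = "power_law_fit")
}

#' Fit an exponential residual-ratio correction
#'
#' Models the ratio of one-parameter-calculated to measured values as
#' prefactor * exp(rate * covariate) by OLS of ln(ratio) on the
#' covariate. The covariate is a composition ratio (accessory pigments
#' per unit chlorophyll, or the inorganic mass fraction of SPM).
#'
#' @param ratio Strictly positive ratios calculated/measured.
#' @param covariate Covariate values, same length.
#' @return List of class `ratio_exponential_fit`: `prefactor`, `rate`,
#'   `n_used`, `n_dropped`, `r_squared`.
#' @export
fit_ratio_exponential <- function(ratio, covariate) {
  stopifnot(length(ratio) == length(covariate))
  keep <- is.finite(ratio) & is.finite(covariate) & ratio > 0
  if (sum(keep) < 2L) {
    stop("fit_ratio_exponential needs at least 2 usable pairs",
         call. = FALSE)
  }
  lr <- log(ratio[keep]); cv <- covariate[keep]
  fit <- stats::lm(lr ~ cv)
  structure(list(
    prefactor = exp(unname(stats::coef(fit)[1])),
    rate = unname(stats::coef(fit)[2]),
    n_used = sum(keep),
    n_dropped = sum(!keep),
    r_squared = r_squared(fit, lr)
  ), class = "ratio_exponential_fit")
}

#' Compose a two-parameter model from a power law and its residual fit
#'
#' The two-parameter constants follow from the one-parameter power law and
#' the exponential fit to the residual ratio cal/meas: dividing the power
#' law by the fitted ratio gives coefficient = c / prefactor, the
#' unchanged exponent, and rate = -residual rate (the correction flips
#' sign when moved from the cal/meas ratio to the model itself).
#'
#' @param one_param A `power_law_fit`.
#' @param residual A `ratio_exponential_fit`.
#' @return List with `coefficient`, `exponent`, `rate`.
#' @export
compose_two_parameter <- function(one_param, residual) {
  list(
    coefficient = one_param$coefficient / residual$prefactor,
    exponent = one_param$exponent,
    rate = -residual$rate
  )
}

#' Fit the CDOM log-polynomial spectrum model
#'
#' Fits log10(a_lambda) = -m u^2 + n u - p with u = log10(a400) by OLS on
#' the design [u^2, u, 1], reporting (m, n, p) in the sign convention of
#' the forward model 10^(-M u^2 + N u - P).
#'
#' @param a400 CDOM absorption at 400 nm (> 0).
#' @param a_lambda CDOM absorption at the target band (> 0).
#' @return List of class `log_poly_fit`: `m`, `n`, `p`, `n_used`,
#'   `n_dropped`.
#' @export
fit_cdom_logpoly <- function(a400, a_lambda) {
  stopifnot(length(a400) == length(a_lambda))
  keep <- is.finite(a400) & is.finite(a_lambda) & a400 > 0 & a_lambda > 0
  if (sum(keep) < 3L) {
    stop("fit_cdom_logpoly needs at least 3 strictly positive pairs",
         call. = FALSE)
  }
  u <- log10(a400[keep]); ly <- log10(a_lambda[keep])
  u2 <- u^2
  fit <- tryCatch(stats::lm(ly ~ u2 + u),
                  error = function(e) stop("CDOM design is collinear",
                                           call. = FALSE))
  cf <- stats::coef(fit)
  if (any(!is.finite(cf))) stop("CDOM design is collinear", call. = FALSE)
  structure(list(
    m = -unname(cf["u2"]),
    n = unname(cf["u"]),
    p = -unname(cf["(Intercept)"]),
    n_used = sum(keep),
    n_dropped = sum(!keep)
  ), class = "log_poly_fit")
}

#' Empirical f/Q for one band from a station table
#'
#' Computes the per-station radiance-distribution factor
#' f/Q = (L_u/E_d) (a + b_b)/b_b from measured radiometry and the
#' measured IOP budget (component absorptions plus pure water), then
#' aggregates over stations (median by default; the median is robust to
#' the heavy tails that log-normal radiometric noise produces).
#'
#' @param stations Station table with radiometry (`lu_<band>`,
#'   `ed_<band>`) and measured IOP columns for the band.
#' @param band One of the model bands.
#' @param coeffs Coefficient set supplying the pure-water terms a_w, b_bw.
#' @param statistic `"median"` or `"mean"`.
#' @return Aggregated f/Q, sr-1.
#' @export
fit_f_over_q <- function(stations, band, coeffs = default_coefficients(),
                         statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  band <- assert_band(band)
  need <- paste0(c("lu_", "ed_", "aph_", "ad_", "acdom_", "bbp_"), band)
  miss <- setdiff(need, names(stations))
  if (length(miss) > 0L) {
    stop("station table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  k <- coef_row(coeffs, band)
  a <- stations[[paste0("aph_", band)]] + stations[[paste0("ad_", band)]] +
    stations[[paste0("acdom_", band)]] + k$a_w
  bb <- stations[[paste0("bbp_", band)]] + k$b_bw
  lu <- stations[[paste0("lu_", band)]]
  ed <- stations[[paste0("ed_", band)]]
  keep <- is.finite(lu) & is.finite(ed) & is.finite(a) & is.finite(bb) &
    ed > 0 & bb > 0 & lu > 0 & a >= 0
  if (!any(keep)) stop("no usable stations for f/Q", call. = FALSE)
  fq <- f_over_q_empirical(lu[keep] / ed[keep], a[keep], bb[keep])
  if (statistic == "median") stats::median(fq) else mean(fq)
}

# joint three-regressor log-space fit of a two-parameter family:
# log10(y) = log10(coef) + exponent*log10(driver) + (rate/ln 10)*ratio
fit_joint_two_param <- function(driver, ratio, y) {
  keep <- is.finite(driver) & is.finite(ratio) & is.finite(y) &
    driver > 0 & y > 0
  if (sum(keep) < 3L) {
    stop("joint fit needs at least 3 usable observations", call. = FALSE)
  }
  ld <- log10(driver[keep]); r <- ratio[keep]; ly <- log10(y[keep])
  fit <- stats::lm(ly ~ ld + r)
  cf <- stats::coef(fit)
  list(coefficient = 10^unname(cf[1]), exponent = unname(cf["ld"]),
       rate = unname(cf["r"]) * log(10),
       n_used = sum(keep), n_dropped = sum(!keep))
}

#' Re-derive the full coefficient set from a station table
#'
#' Reproduces the three-stage fitting procedure behind the five-parameter
#' model: (1) one-parameter power laws per component family and band;
#' (2) exponential fits of the residual ratio calculated/measured against
#' a composition covariate; (3) composition into the two-parameter
#' constants; plus the CDOM log-polynomial fits and the empirical f/Q per
#' band. The pure-water terms a_w and b_bw are physical constants and are
#' carried over from `reference`, not fitted.
#'
#' Covariate guards: stations whose accessory-pigment ratio falls outside
#' \[0, 2\] or whose inorganic fraction falls outside \[0, 1\] are excluded
#' from the residual fits, and the exclusions counted.
#'
#' @param stations Station table with constituent and measured IOP
#'   columns (radiometry optional; without it the f/Q step is skipped
#'   with a warning and the reference values retained).
#' @param method `"two_step"` (the historical procedure: power law, then
#'   residual correction) or `"joint"` (single three-regressor log-space
#'   OLS per family; exactly recovers generating constants on noiseless
#'   data).
#' @param f_over_q_stat Aggregation statistic for f/Q.
#' @param reference Coefficient set supplying a_w and b_bw (and f/Q when
#'   radiometry is absent).
#' @return List of class `calibration_result` with elements
#'   `coefficients` (an [rrs_coefficients] table), `one_param`,
#'   `residual`, `cdom`, `f_over_q`, `method` and `diagnostics`.
#' @export
calibrate_all <- function(stations,
                          method = c("two_step", "joint"),
                          f_over_q_stat = c("median", "mean"),
                          reference = default_coefficients()) {
  method <- match.arg(method)
  f_over_q_stat <- match.arg(f_over_q_stat)
  const_cols <- c("chl_a_mg_m3", "sum_c_mg_m3", "spm_g_m3",
                  "spm_inorg_g_m3", "a_cdom_400_m1")
  miss <- setdiff(const_cols, names(stations))
  if (length(miss) > 0L) {
    stop("station table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  chl <- stations$chl_a_mg_m3
  spm <- stations$spm_g_m3
  pig_ratio <- ifelse(chl > 0, stations$sum_c_mg_m3 / chl, NA_real_)
  inorg_frac <- ifelse(spm > 0, stations$spm_inorg_g_m3 / spm, NA_real_)
  pig_ok <- is.finite(pig_ratio) & pig_ratio >= 0 & pig_ratio <= 2
  frac_ok <- is.finite(inorg_frac) & inorg_frac >= 0 & inorg_frac <= 1

  families <- list(
    aph = list(driver = chl, ratio = pig_ratio, guard = pig_ok,
               prefix = "aph"),
    ad = list(driver = spm, ratio = inorg_frac, guard = frac_ok,
              prefix = "ad"),
    bbp = list(driver = spm, ratio = inorg_frac, guard = frac_ok,
               prefix = "bbp")
  )

  one_param <- list(); residual <- list(); two_param <- list()
  cdom <- list()
  diag <- list(covariate_excluded = c(aph = sum(!pig_ok),
                                      particles = sum(!frac_ok)))

  for (fam in names(families)) {
    f <- families[[fam]]
    for (band in rrs_bands()) {
      mcol <- paste0(f$prefix, "_", band)
      if (!mcol %in% names(stations)) {
        stop(sprintf("station table has no measured column `%s`", mcol),
             call. = FALSE)
      }
      y <- stations[[mcol]]
      key <- paste0(fam, "_", band)
      if (method == "joint") {
        jf <- fit_joint_two_param(f$driver[f$guard], f$ratio[f$guard],
                                  y[f$guard])
        two_param[[key]] <- jf[c("coefficient", "exponent", "rate")]
      } else {
        pf <- fit_power_law(f$driver, y)
        one_param[[key]] <- pf
        cal1 <- pf$coefficient * f$driver^pf$exponent
        use <- f$guard & is.finite(y) & y > 0
        rf <- fit_ratio_exponential((cal1 / y)[use], f$ratio[use])
        residual[[key]] <- rf
        two_param[[key]] <- compose_two_parameter(pf, rf)
      }
    }
  }

  for (band in rrs_bands()) {
    mcol <- paste0("acdom_", band)
    if (!mcol %in% names(stations)) {
      stop(sprintf("station table has no measured column `%s`", mcol),
           call. = FALSE)
    }
    cdom[[as.character(band)]] <-
      fit_cdom_logpoly(stations$a_cdom_400_m1, stations[[mcol]])
  }

  have_radiometry <- all(paste0(c("lu_", "ed_"), rep(rrs_bands(),
                                                     each = 2)) %in%
                           names(stations))
  if (have_radiometry) {
    fq <- vapply(rrs_bands(), function(b)
      fit_f_over_q(stations, b, reference, f_over_q_stat), numeric(1))
  } else {
    warning("station table carries no radiometry; f/Q step skipped, ",
            "reference values retained", call. = FALSE)
    fq <- reference$f_over_q
  }

  tp <- function(fam, what) {
    vapply(rrs_bands(), function(b)
      two_param[[paste0(fam, "_", b)]][[what]], numeric(1))
  }
  cd <- function(what) {
    vapply(rrs_bands(), function(b) cdom[[as.character(b)]][[what]],
           numeric(1))
  }
  coeffs <- rrs_coefficients(data.frame(
    band = rrs_bands(),
    C = tp("bbp", "coefficient"), B = tp("bbp", "exponent"),
    D = tp("bbp", "rate"),
    G = tp("aph", "coefficient"), F = tp("aph", "exponent"),
    H = tp("aph", "rate"),
    K = tp("ad", "coefficient"), J = tp("ad", "exponent"),
    L = tp("ad", "rate"),
    M = cd("m"), N = cd("n"), P = cd("p"),
    a_w = reference$a_w, b_bw = reference$b_bw,
    f_over_q = fq
  ))

  structure(list(
    coefficients = coeffs,
    one_param = one_param,
    residual = residual,
    cdom = cdom,
    f_over_q = stats::setNames(fq, rrs_bands()),
    method = method,
    f_over_q_stat = f_over_q_stat,
    n_stations = nrow(stations),
    diagnostics = diag
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration of the five-parameter Rrs model (%s fit, %d stations)\n",
              x$method, x$n_stations))
  print(x$coefficients)
  invisible(x)
}
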