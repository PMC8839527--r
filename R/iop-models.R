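#' Component IOP models
#'
#' One- and two-parameter regression models linking the inherent optical
#' properties of southern-Baltic coastal water to five biogeochemical
#' drivers: chlorophyll a (`chl_a`, mg m-3), the sum of accessory pigment
#' concentrations (`sum_c`, mg m-3), suspended particulate matter (`spm`,
#' g m-3) and its inorganic fraction (`spm_inorg`, g m-3), and CDOM
#' absorption at the 400 nm reference wavelength (`a_cdom_400`, m-1).
#' All absorption and backscattering outputs are in m-1.
#'
#' The one-parameter forms are power laws in the single driver. The
#' two-parameter forms multiply the power law by an exponential in a
#' composition ratio (accessory pigments per unit chlorophyll for
#' phytoplankton; inorganic mass fraction for particles), which absorbs
#' the part of the scatter the single driver cannot explain. The CDOM
#' model is a quadratic in u = log10(a_cdom_400) on the log10 scale.
#'
#' @param chl_a Chlorophyll a concentration, mg m-3 (vectorised, >= 0).
#' @param sum_c Sum of accessory pigment concentrations, mg m-3 (>= 0;
#'   must be 0 wherever `chl_a` is 0).
#' @param spm Suspended particulate matter dry mass, g m-3 (>= 0).
#' @param spm_inorg Inorganic SPM fraction dry mass, g m-3
#'   (0 <= spm_inorg <= spm).
#' @param a_cdom_400 CDOM absorption at 400 nm, m-1 (>= 0).
#' @param band One of 420, 488, 555, 620 (nm).
#' @param coeffs An [rrs_coefficients] set; defaults to the shipped
#'   southern-Baltic constants.
#' @return Numeric vector of absorption or backscattering values, m-1.
#' @name iop_models
NULL

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and >= 0", what), call. = FALSE)
  }
  x
}

# ratio numerator/denominator with the degenerate 0/0 case defined as 0;
# positive numerator over zero denominator is a domain error
safe_ratio <- function(num, den, num_name, den_name) {
  if (any(num > 0 & den == 0)) {
    stop(sprintf("`%s` > 0 where `%s` = 0: ratio %s/%s diverges",
                 num_name, den_name, num_name, den_name), call. = FALSE)
  }
  r <- rep(0, length(den))
  ok <- den > 0
  r[ok] <- num[ok] / den[ok]
  r
}

#' @rdname iop_models
#' @export
aph_one_param <- function(chl_a, band) {
  band <- assert_band(band)
  check_nonneg(chl_a, "chl_a")
  k <- one_param_coefficients()
  i <- match(band, k$band)
  k$aph_c[i] * chl_a^k$aph_e[i]
}

#' @rdname iop_models
#' @export
ad_one_param <- function(spm, band) {
  band <- assert_band(band)
  check_nonneg(spm, "spm")
  k <- one_param_coefficients()
  i <- match(band, k$band)
  k$ad_c[i] * spm^k$ad_e[i]
}

#' @rdname iop_models
#' @export
bbp_one_param <- function(spm, band) {
  band <- assert_band(band)
  check_nonneg(spm, "spm")
  k <- one_param_coefficients()
  i <- match(band, k$band)
  k$bbp_c[i] * spm^k$bbp_e[i]
}

#' @rdname iop_models
#' @details
#' `acdom_model()` evaluates \eqn{10^{-M u^2 + N u - P}} with
#' \eqn{u = \log_{10} a_{CDOM}(400)}. At `a_cdom_400 = 0` the value is 0,
#' the continuous limit (the -M u^2 term dominates as u -> -Inf). The
#' quadratic argument is the log of the driver, not the driver itself: the
#' raw-argument reading would make a_CDOM grow from 400 to 420 nm, which
#' CDOM spectra never do.
#' @export
acdom_model <- function(a_cdom_400, band, coeffs = default_coefficients()) {
  band <- assert_band(band)
  check_nonneg(a_cdom_400, "a_cdom_400")
  k <- coef_row(coeffs, band)
  out <- numeric(length(a_cdom_400))
  pos <- a_cdom_400 > 0
  u <- log10(a_cdom_400[pos])
  out[pos] <- 10^(-k$M * u^2 + k$N * u - k$P)
  out
}

#' @rdname iop_models
#' @export
aph_two_param <- function(chl_a, sum_c, band, coeffs = default_coefficients()) {
  band <- assert_band(band)
  check_nonneg(chl_a, "chl_a")
  check_nonneg(sum_c, "sum_c")
  stopifnot(length(chl_a) == length(sum_c))
  r <- safe_ratio(sum_c, chl_a, "sum_c", "chl_a")
  k <- coef_row(coeffs, band)
  k$G * chl_a^k$F * exp(k$H * r)
}

#' @rdname iop_models
#' @export
ad_two_param <- function(spm, spm_inorg, band, coeffs = default_coefficients()) {
  band <- assert_band(band)
  check_nonneg(spm, "spm")
  check_nonneg(spm_inorg, "spm_inorg")
  stopifnot(length(spm) == length(spm_inorg))
  if (any(spm_inorg > spm)) {
    stop("`spm_inorg` must not exceed `spm`", call. = FALSE)
  }
  r <- safe_ratio(spm_inorg, spm, "spm_inorg", "spm")
  k <- coef_row(coeffs, band)
  k$K * spm^k$J * exp(k$L * r)
}

#' @rdname iop_models
#' @export
bbp_two_param <- function(spm, spm_inorg, band, coeffs = default_coefficients()) {
  band <- assert_band(band)
  check_nonneg(spm, "spm")
  check_nonneg(spm_inorg, "spm_inorg")
  stopifnot(length(spm) == length(spm_inorg))
  if (any(spm_inorg > spm)) {
    stop("`spm_inorg` must not exceed `spm`", call. = FALSE)
  }
  r <- safe_ratio(spm_inorg, spm, "spm_inorg", "spm")
  k <- coef_row(coeffs, band)
  k$C * spm^k$B * exp(k$D * r)
}
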