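#' Constituent vector for the five-parameter model
#'
#' Bundles the five model drivers for one or more stations and validates
#' the physical constraints: non-negative concentrations, inorganic SPM
#' not exceeding total SPM, and accessory pigments only in the presence of
#' chlorophyll (the ratio sum_c/chl_a must stay finite).
#'
#' @param chl_a Chlorophyll a, mg m-3.
#' @param sum_c Sum of accessory pigments, mg m-3.
#' @param spm Suspended particulate matter, g m-3.
#' @param spm_inorg Inorganic SPM, g m-3.
#' @param a_cdom_400 CDOM absorption at 400 nm, m-1.
#' @return Data frame of class `constituents` with the five columns,
#'   recycled to a common length.
#' @export
#' @examples
#' constituents(chl_a = 5, sum_c = 1.5, spm = 4, spm_inorg = 1.6,
#'              a_cdom_400 = 0.8)
constituents <- function(chl_a, sum_c, spm, spm_inorg, a_cdom_400) {
  cv <- data.frame(chl_a = chl_a, sum_c = sum_c, spm = spm,
                   spm_inorg = spm_inorg, a_cdom_400 = a_cdom_400)
  for (nm in names(cv)) check_nonneg(cv[[nm]], nm)
  if (any(cv$spm_inorg > cv$spm)) {
    stop("`spm_inorg` must not exceed `spm`", call. = FALSE)
  }
  if (any(cv$sum_c > 0 & cv$chl_a == 0)) {
    stop("`sum_c` > 0 requires `chl_a` > 0", call. = FALSE)
  }
  class(cv) <- c("constituents", "data.frame")
  cv
}

as_constituents <- function(cv) {
  if (inherits(cv, "constituents")) return(cv)
  needed <- c("chl_a", "sum_c", "spm", "spm_inorg", "a_cdom_400")
  miss <- setdiff(needed, names(cv))
  if (length(miss) > 0L) {
    stop("constituent table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  do.call(constituents, as.list(cv[needed]))
}

#' Total absorption budget
#'
#' Sum of the absorption budget at one band: phytoplankton + non-algal
#' particles + CDOM (each from its two-parameter/CDOM component model)
#' plus pure seawater `a_w`. Always at least `a_w`.
#'
#' @param cv A [constituents] object (or data frame with its columns).
#' @inheritParams iop_models
#' @return Total absorption, m-1 (vector over stations).
#' @export
a_total <- function(cv, band, coeffs = default_coefficients()) {
  cv <- as_constituents(cv)
  band <- assert_band(band)
  aph_two_param(cv$chl_a, cv$sum_c, band, coeffs) +
    ad_two_param(cv$spm, cv$spm_inorg, band, coeffs) +
    acdom_model(cv$a_cdom_400, band, coeffs) +
    coef_row(coeffs, band)$a_w
}

#' Total backscattering budget
#'
#' Particulate backscattering (two-parameter model) plus pure seawater
#' `b_bw`. Always at least `b_bw`.
#'
#' @inheritParams a_total
#' @return Total backscattering, m-1.
#' @export
bb_total <- function(cv, band, coeffs = default_coefficients()) {
  cv <- as_constituents(cv)
  band <- assert_band(band)
  bbp_two_param(cv$spm, cv$spm_inorg, band, coeffs) +
    coef_row(coeffs, band)$b_bw
}

#' Forward five-parameter remote-sensing reflectance
#'
#' Evaluates the semi-empirical model
#' \deqn{R_{rs}(\lambda_i) = (f/Q)(\lambda_i)\,
#'   \frac{b_b(\lambda_i)}{a(\lambda_i) + b_b(\lambda_i)}}
#' with `a` and `b_b` from the component budgets. The result lies strictly
#' between 0 and f/Q for any valid input; with all constituents zero it
#' reduces to the clear-water value (f/Q) b_bw / (a_w + b_bw).
#'
#' @inheritParams a_total
#' @return Remote-sensing reflectance just below the surface, sr-1.
#' @export
#' @examples
#' cv <- constituents(5, 1.5, 4, 1.6, 0.8)
#' rrs_forward(cv, 488)
rrs_forward <- function(cv, band, coeffs = default_coefficients()) {
  band <- assert_band(band)
  a <- a_total(cv, band, coeffs)
  bb <- bb_total(cv, band, coeffs)
  coef_row(coeffs, band)$f_over_q * bb / (a + bb)
}

#' Reflectance and Q factor from underwater radiometry
#'
#' `rrs_from_radiometry()` forms R_rs = L_u(0-) / E_d(0-) from upwelling
#' radiance and downwelling irradiance just below the surface;
#' `q_factor()` forms Q = E_u(0-) / L_u(0-), the measure of non-isotropy
#' of the upward radiance field (sr).
#'
#' @param l_u0m Upwelling radiance just below the surface.
#' @param e_d0m Downwelling irradiance just below the surface (> 0).
#' @param e_u0m Upwelling irradiance just below the surface.
#' @return Reflectance (sr-1) or Q (sr), vectorised.
#' @export
rrs_from_radiometry <- function(l_u0m, e_d0m) {
  if (any(!is.finite(e_d0m)) || any(e_d0m <= 0)) {
    stop("`e_d0m` must be > 0", call. = FALSE)
  }
  check_nonneg(l_u0m, "l_u0m")
  l_u0m / e_d0m
}

#' @rdname rrs_from_radiometry
#' @export
q_factor <- function(e_u0m, l_u0m) {
  if (any(!is.finite(l_u0m)) || any(l_u0m <= 0)) {
    stop("`l_u0m` must be > 0", call. = FALSE)
  }
  check_nonneg(e_u0m, "e_u0m")
  e_u0m / l_u0m
}

#' Empirical f/Q from reflectance and the IOP budget
#'
#' Inverts the reflectance model for the radiance-distribution factor:
#' f/Q = R_rs (a + b_b) / b_b. Applied to measured reflectance with
#' measured (or modelled) total absorption and backscattering, this yields
#' the per-station empirical f/Q that the calibration aggregates per band.
#'
#' @param r_rs Remote-sensing reflectance, sr-1.
#' @param a Total absorption, m-1 (>= 0).
#' @param b_b Total backscattering, m-1 (> 0).
#' @return f/Q, sr-1 (vectorised).
#' @export
f_over_q_empirical <- function(r_rs, a, b_b) {
  check_nonneg(a, "a")
  if (any(!is.finite(b_b)) || any(b_b <= 0)) {
    stop("`b_b` must be > 0", call. = FALSE)
  }
  r_rs * (a + b_b) / b_b
}
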