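#' Population parameters for the synthetic station generator
#'
#' Describes a synthetic population of coastal stations with the
#' statistical structure of southern-Baltic (Case 2) field data:
#' lognormal marginals for chlorophyll a, SPM and CDOM absorption at
#' 400 nm (each spanning orders of magnitude across the population), a
#' beta-distributed inorganic mass fraction of SPM, a truncated-normal
#' accessory-pigment-to-chlorophyll ratio, and multiplicative lognormal
#' measurement noise on IOPs and upwelling radiance.
#'
#' The default marginals are calibrated so that the generated absorption
#' budget at 420 nm reproduces the observed Baltic coastal split of
#' non-water absorption — on average roughly 68% CDOM, 20% phytoplankton
#' and 12% non-algal particles. The default noise level
#' (sigma_log10 = 0.14, a standard error factor of 10^0.14 ~ 1.38) sits
#' in the range reported for coastal IOP regressions.
#'
#' @param n Number of stations (>= 1).
#' @param chl_median,chl_sigma_log10 Median (mg m-3) and log10-spread of
#'   chlorophyll a.
#' @param spm_median,spm_sigma_log10 Median (g m-3) and log10-spread of
#'   SPM.
#' @param acdom400_median,acdom400_sigma_log10 Median (m-1) and
#'   log10-spread of a_CDOM(400).
#' @param inorg_beta Length-2 shape pair of the beta distribution of the
#'   inorganic SPM fraction.
#' @param pig_ratio_mean,pig_ratio_sd,pig_ratio_range Mean, sd and
#'   truncation interval of the accessory-pigment ratio sum_c/chl_a.
#' @param iop_noise_sigma_log10 Multiplicative lognormal noise on each
#'   measured IOP (decades).
#' @param lu_noise_sigma_log10 Multiplicative lognormal noise on
#'   upwelling radiance (decades).
#' @param e_d_scale Median downwelling irradiance (relative energy
#'   units).
#' @param q_sr Q = E_u/L_u factor used when synthesising upwelling
#'   irradiance (sr).
#' @return Validated list of class `population_params`.
#' @export
population_params <- function(n = 200L,
                              chl_median = 5, chl_sigma_log10 = 0.4,
                              spm_median = 1.5, spm_sigma_log10 = 0.35,
                              acdom400_median = 1.0,
                              acdom400_sigma_log10 = 0.2,
                              inorg_beta = c(2, 3),
                              pig_ratio_mean = 0.35, pig_ratio_sd = 0.1,
                              pig_ratio_range = c(0.05, 1),
                              iop_noise_sigma_log10 = 0.14,
                              lu_noise_sigma_log10 = 0.14,
                              e_d_scale = 1,
                              q_sr = 4) {
  p <- list(n = as.integer(n), chl_median = chl_median,
            chl_sigma_log10 = chl_sigma_log10, spm_median = spm_median,
            spm_sigma_log10 = spm_sigma_log10,
            acdom400_median = acdom400_median,
            acdom400_sigma_log10 = acdom400_sigma_log10,
            inorg_beta = inorg_beta, pig_ratio_mean = pig_ratio_mean,
            pig_ratio_sd = pig_ratio_sd,
            pig_ratio_range = pig_ratio_range,
            iop_noise_sigma_log10 = iop_noise_sigma_log10,
            lu_noise_sigma_log10 = lu_noise_sigma_log10,
            e_d_scale = e_d_scale, q_sr = q_sr)
  if (p$n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (any(c(p$chl_median, p$spm_median, p$acdom400_median,
            p$e_d_scale, p$q_sr) <= 0)) {
    stop("medians, e_d_scale and q_sr must be > 0", call. = FALSE)
  }
  if (any(c(p$chl_sigma_log10, p$spm_sigma_log10,
            p$acdom400_sigma_log10, p$pig_ratio_sd) <= 0)) {
    stop("spreads must be > 0", call. = FALSE)
  }
  if (length(p$inorg_beta) != 2L || any(p$inorg_beta <= 0)) {
    stop("`inorg_beta` must be two positive shapes", call. = FALSE)
  }
  if (length(p$pig_ratio_range) != 2L || p$pig_ratio_range[1] <= 0 ||
      p$pig_ratio_range[2] > 2 ||
      p$pig_ratio_range[1] >= p$pig_ratio_range[2]) {
    stop("`pig_ratio_range` must be an increasing interval in (0, 2]",
         call. = FALSE)
  }
  if (any(c(p$iop_noise_sigma_log10, p$lu_noise_sigma_log10) < 0)) {
    stop("noise levels must be >= 0", call. = FALSE)
  }
  class(p) <- "population_params"
  p
}

# run code with a local RNG state so generators never disturb (or depend
# on) the caller's random stream
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an explicit integer `seed` is required", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

rtruncnorm_inv <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate synthetic constituent vectors
#'
#' Draws `n` stations from the configured population: chlorophyll a, SPM
#' and a_CDOM(400) lognormal; inorganic SPM as a beta-distributed
#' fraction of SPM; accessory pigments as a truncated-normal ratio of
#' chlorophyll. Every generated row satisfies the constituent invariants
#' by construction.
#'
#' @param params A [population_params] object.
#' @param seed Integer seed (required; generation is fully reproducible).
#' @return Data frame with columns `station_id`, `chl_a_mg_m3`,
#'   `sum_c_mg_m3`, `spm_g_m3`, `spm_inorg_g_m3`, `a_cdom_400_m1`.
#' @export
generate_constituents <- function(params = population_params(), seed) {
  stopifnot(inherits(params, "population_params"))
  with_seed(seed, {
    n <- params$n
    chl <- 10^stats::rnorm(n, log10(params$chl_median),
                           params$chl_sigma_log10)
    spm <- 10^stats::rnorm(n, log10(params$spm_median),
                           params$spm_sigma_log10)
    a400 <- 10^stats::rnorm(n, log10(params$acdom400_median),
                            params$acdom400_sigma_log10)
    frac <- stats::rbeta(n, params$inorg_beta[1], params$inorg_beta[2])
    ratio <- rtruncnorm_inv(n, params$pig_ratio_mean, params$pig_ratio_sd,
                            params$pig_ratio_range[1],
                            params$pig_ratio_range[2])
    data.frame(
      station_id = sprintf("S%04d", seq_len(n)),
      chl_a_mg_m3 = chl,
      sum_c_mg_m3 = chl * ratio,
      spm_g_m3 = spm,
      spm_inorg_g_m3 = spm * frac,
      a_cdom_400_m1 = a400
    )
  })
}

#' Add synthetic measured IOP columns
#'
#' For each station and band, the "measured" IOP is the forward-model
#' value perturbed by multiplicative lognormal noise:
#' measured = model * 10^(sigma * z) with z standard normal, drawn
#' independently per station, band and quantity. With sigma = 0 the
#' measured columns equal the model exactly.
#'
#' @param stations Data frame with the constituent columns.
#' @param coeffs Coefficient set generating the true IOPs.
#' @param noise_sigma_log10 Noise level (decades), >= 0.
#' @param seed Integer seed.
#' @return `stations` with 16 added columns `aph_<band>`, `ad_<band>`,
#'   `acdom_<band>`, `bbp_<band>`.
#' @export
synthesize_iops <- function(stations, coeffs = default_coefficients(),
                            noise_sigma_log10 = 0, seed) {
  if (noise_sigma_log10 < 0) stop("noise must be >= 0", call. = FALSE)
  cv <- station_constituents(stations)
  with_seed(seed, {
    n <- nrow(stations)
    for (band in rrs_bands()) {
      truth <- list(
        aph = aph_two_param(cv$chl_a, cv$sum_c, band, coeffs),
        ad = ad_two_param(cv$spm, cv$spm_inorg, band, coeffs),
        acdom = acdom_model(cv$a_cdom_400, band, coeffs),
        bbp = bbp_two_param(cv$spm, cv$spm_inorg, band, coeffs)
      )
      for (q in names(truth)) {
        noisy <- truth[[q]] *
          10^(noise_sigma_log10 * stats::rnorm(n))
        stations[[paste0(q, "_", band)]] <- noisy
      }
    }
    stations
  })
}

#' Add synthetic underwater radiometry
#'
#' Inverts the radiometric definitions consistently: the station's true
#' reflectance comes from the forward model on its constituents, then
#' L_u = R_rs * E_d (optionally perturbed by lognormal noise) and
#' E_u = Q * L_u. Downwelling irradiance varies lognormally around
#' `e_d_scale` to emulate changing illumination between stations. The
#' recorded `rrs_<band>` column is L_u/E_d row-wise, so the reflectance
#' definition holds identically in the output.
#'
#' @param stations Data frame with constituent columns.
#' @param coeffs Coefficient set (supplies f/Q and the IOP models).
#' @param q_sr Q = E_u/L_u (sr), > 0.
#' @param e_d_scale Median downwelling irradiance, > 0.
#' @param lu_noise_sigma_log10 Lognormal noise on L_u (decades), >= 0.
#' @param seed Integer seed.
#' @return `stations` with 16 added columns `lu_<band>`, `ed_<band>`,
#'   `eu_<band>`, `rrs_<band>`.
#' @export
synthesize_radiometry <- function(stations,
                                  coeffs = default_coefficients(),
                                  q_sr = 4, e_d_scale = 1,
                                  lu_noise_sigma_log10 = 0, seed) {
  if (q_sr <= 0 || e_d_scale <= 0) {
    stop("`q_sr` and `e_d_scale` must be > 0", call. = FALSE)
  }
  if (lu_noise_sigma_log10 < 0) stop("noise must be >= 0", call. = FALSE)
  cv <- station_constituents(stations)
  with_seed(seed, {
    n <- nrow(stations)
    ed <- e_d_scale * 10^(0.1 * stats::rnorm(n))
    for (band in rrs_bands()) {
      rrs_true <- rrs_forward(cv, band, coeffs)
      lu <- rrs_true * ed *
        10^(lu_noise_sigma_log10 * stats::rnorm(n))
      stations[[paste0("lu_", band)]] <- lu
      stations[[paste0("ed_", band)]] <- ed
      stations[[paste0("eu_", band)]] <- q_sr * lu
      stations[[paste0("rrs_", band)]] <- lu / ed
    }
    stations
  })
}

#' Generate a complete synthetic station table
#'
#' End-to-end composition of the three generators: constituents, noisy
#' measured IOPs, and radiometry. Two calls with the same parameters and
#' seed produce identical tables.
#'
#' @param params A [population_params] object.
#' @param coeffs Coefficient set generating the optics.
#' @param seed Integer seed.
#' @return A full station table (see [station_schema()]).
#' @export
#' @examples
#' tbl <- generate_dataset(population_params(n = 50), seed = 1)
#' head(tbl[, 1:6])
generate_dataset <- function(params = population_params(),
                             coeffs = default_coefficients(), seed) {
  stopifnot(inherits(params, "population_params"))
  tbl <- generate_constituents(params, seed = seed)
  tbl <- synthesize_iops(tbl, coeffs,
                         noise_sigma_log10 = params$iop_noise_sigma_log10,
                         seed = seed + 1L)
  tbl <- synthesize_radiometry(tbl, coeffs, q_sr = params$q_sr,
                               e_d_scale = params$e_d_scale,
                               lu_noise_sigma_log10 =
                                 params$lu_noise_sigma_log10,
                               seed = seed + 2L)
  tbl[station_schema()]
}

#' Mean component shares of non-water absorption
#'
#' For each station the share of CDOM, phytoplankton and non-algal
#' particles in non-water absorption at one band, averaged over stations
#' — the synthetic counterpart of the observed Baltic absorption budget
#' (~68/20/12 CDOM/phytoplankton/detritus at 420 nm).
#'
#' @param stations Station table (constituent columns suffice).
#' @param band Model band.
#' @param coeffs Coefficient set.
#' @return Named numeric vector (percent): `cdom`, `aph`, `ad`.
#' @export
absorption_budget <- function(stations, band = 420,
                              coeffs = default_coefficients()) {
  cv <- station_constituents(stations)
  band <- assert_band(band)
  aph <- aph_two_param(cv$chl_a, cv$sum_c, band, coeffs)
  ad <- ad_two_param(cv$spm, cv$spm_inorg, band, coeffs)
  acd <- acdom_model(cv$a_cdom_400, band, coeffs)
  tot <- aph + ad + acd
  c(cdom = 100 * mean(acd / tot),
    aph = 100 * mean(aph / tot),
    ad = 100 * mean(ad / tot))
}
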