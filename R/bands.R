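#' Model wavelength bands
#'
#' The semi-empirical reflectance model is defined at exactly four
#' wavelengths, dictated by the backscattering meter channels used to build
#' it: 420, 488, 555 and 620 nm. Every band-indexed function in the package
#' rejects any other wavelength rather than interpolating.
#'
#' @return Integer vector `c(420L, 488L, 555L, 620L)`.
#' @export
#' @examples
#' rrs_bands()
rrs_bands <- function() c(420L, 488L, 555L, 620L)

#' Check that a wavelength is one of the four model bands
#'
#' @param band Integer scalar wavelength in nm.
#' @return The band, invisibly, as an integer.
#' @keywords internal
assert_band <- function(band) {
  if (length(band) != 1L || !is.numeric(band) || is.na(band)) {
    stop("`band` must be a single wavelength in nm", call. = FALSE)
  }
  band <- as.integer(band)
  if (!band %in% rrs_bands()) {
    stop(sprintf(
      "band %d nm is not a model band; the model is defined only at %s nm",
      band, paste(rrs_bands(), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(band)
}

#' Nearest radiometer channel for a model band
#'
#' Radiometers rarely sample exactly at the model bands; profiling
#' instruments used for Baltic reflectance work report e.g. 412, 443, 490,
#' 510, 555, 670 and 683 nm. This helper implements nearest-neighbour
#' channel selection, with ties broken toward the shorter wavelength so the
#' mapping is deterministic.
#'
#' @param wavelength_nm Target wavelength (nm), numeric scalar.
#' @param channels Non-empty numeric vector of available channel
#'   wavelengths (nm).
#' @return The element of `channels` closest to `wavelength_nm`.
#' @export
#' @examples
#' nearest_band(420, c(412, 443, 490, 510, 555, 670, 683))
nearest_band <- function(wavelength_nm, channels) {
  if (length(channels) == 0L) stop("`channels` must be non-empty", call. = FALSE)
  stopifnot(is.numeric(wavelength_nm), length(wavelength_nm) == 1L,
            is.numeric(channels))
  d <- abs(channels - wavelength_nm)
  hits <- channels[d == min(d)]
  min(hits)
}
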