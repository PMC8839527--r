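#' Coefficient set of the five-parameter reflectance model
#'
#' Container for the per-band constants of the five-parameter Rrs model:
#' the particulate backscattering constants (C, B, D), phytoplankton
#' absorption constants (G, F, H), non-algal particle absorption constants
#' (K, J, L), the CDOM log-polynomial constants (M, N, P), pure seawater
#' absorption `a_w` and backscattering `b_bw` (both in m-1), and the f/Q
#' radiance-distribution factor (sr-1).
#'
#' The component models read, per band i:
#' \deqn{b_{bp} = C \cdot SPM^{B} e^{D \cdot SPM_{inorg}/SPM}}
#' \deqn{a_{ph} = G \cdot Chl^{F} e^{H \cdot \Sigma C / Chl}}
#' \deqn{a_{d}  = K \cdot SPM^{J} e^{L \cdot SPM_{inorg}/SPM}}
#' \deqn{a_{CDOM} = 10^{-M u^2 + N u - P},\quad u = \log_{10} a_{CDOM}(400)}
#'
#' @param tbl Data frame with one row per band and columns `band`, `C`,
#'   `B`, `D`, `G`, `F`, `H`, `K`, `J`, `L`, `M`, `N`, `P`, `a_w`, `b_bw`,
#'   `f_over_q`.
#' @return An object of class `rrs_coefficients` (a validated data frame).
#' @seealso [default_coefficients()] for the shipped southern-Baltic set,
#'   [read_coefficients()] / [write_coefficients()] for JSON round-trips.
#' @export
rrs_coefficients <- function(tbl) {
  needed <- c("band", "C", "B", "D", "G", "F", "H", "K", "J", "L",
              "M", "N", "P", "a_w", "b_bw", "f_over_q")
  miss <- setdiff(needed, names(tbl))
  if (length(miss) > 0L) {
    stop("coefficient table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl <- as.data.frame(tbl)[needed]
  tbl$band <- as.integer(tbl$band)
  if (!setequal(tbl$band, rrs_bands()) || nrow(tbl) != 4L) {
    stop("coefficient table must contain exactly the four bands ",
         paste(rrs_bands(), collapse = ", "), " nm", call. = FALSE)
  }
  tbl <- tbl[order(tbl$band), , drop = FALSE]
  rownames(tbl) <- NULL
  num <- as.matrix(tbl[setdiff(needed, "band")])
  if (any(!is.finite(num))) {
    stop("all coefficients must be finite", call. = FALSE)
  }
  # rate constants (D, H, L) may legitimately be fitted near or below
  # zero on noisy data; everything else must stay positive
  pos <- c("C", "B", "G", "F", "K", "J", "a_w", "b_bw", "f_over_q")
  if (any(as.matrix(tbl[pos]) <= 0)) {
    stop("power-law constants, pure-water terms and f/Q must be > 0",
         call. = FALSE)
  }
  class(tbl) <- c("rrs_coefficients", "data.frame")
  tbl
}

#' Shipped southern-Baltic coefficient set
#'
#' The published constants of the five-parameter model for southern-Baltic
#' coastal waters, including pure-seawater absorption and backscattering
#' and the empirical f/Q values (0.07, 0.10, 0.12 and 0.13 sr-1 at 420,
#' 488, 555 and 620 nm; f/Q increases with wavelength in these waters).
#'
#' @return An `rrs_coefficients` object with one row per band.
#' @export
#' @examples
#' default_coefficients()
default_coefficients <- function() {
  rrs_coefficients(data.frame(
    band = c(420L, 488L, 555L, 620L),
    C = c(0.009, 0.006, 0.005, 0.004),
    B = c(0.911, 0.891, 0.935, 0.881),
    D = c(0.337, 0.827, 0.977, 1.230),
    G = c(0.041, 0.022, 0.011, 0.007),
    F = c(0.827, 0.820, 0.815, 0.926),
    H = c(0.493, 0.824, 0.257, 0.261),
    K = c(0.057, 0.035, 0.022, 0.015),
    J = c(0.807, 0.762, 0.646, 0.592),
    L = c(0.750, 0.903, 1.157, 1.542),
    M = c(0.077, 0.624, 1.037, 1.488),
    N = c(1.006, 1.077, 1.072, 1.136),
    P = c(0.132, 0.485, 0.689, 0.794),
    a_w = c(0.0045, 0.0147, 0.0596, 0.2755),
    b_bw = c(0.0023, 0.0012, 0.0007, 0.0004),
    f_over_q = c(0.07, 0.10, 0.12, 0.13)
  ))
}

#' One-parameter component-model constants
#'
#' Power-law constants of the single-driver component models: a_ph from
#' Chl a, a_d from SPM, b_bp from SPM. These keep their own published
#' values and are not recomputed from the two-parameter set.
#'
#' Note: the printed a_d coefficient 0.002 at 620 nm breaks the monotone
#' trend of the other bands and is inconsistent with the two-parameter
#' value (0.015); it is retained as published, but treat a_d(620)
#' one-parameter predictions with caution.
#'
#' @return Data frame with columns `band`, `aph_c`, `aph_e`, `ad_c`,
#'   `ad_e`, `bbp_c`, `bbp_e` (coefficient and exponent per family).
#' @export
one_param_coefficients <- function() {
  data.frame(
    band = c(420L, 488L, 555L, 620L),
    aph_c = c(0.056, 0.037, 0.013, 0.008),
    aph_e = c(0.827, 0.820, 0.815, 0.926),
    ad_c = c(0.071, 0.045, 0.031, 0.002),
    ad_e = c(0.809, 0.762, 0.646, 0.592),
    bbp_c = c(0.011, 0.008, 0.007, 0.005),
    bbp_e = c(0.911, 0.891, 0.935, 0.881)
  )
}

# Row of a coefficient table for one band, as a one-row list.
coef_row <- function(coeffs, band) {
  band <- assert_band(band)
  as.list(coeffs[match(band, coeffs$band), , drop = FALSE])
}

#' @export
print.rrs_coefficients <- function(x, ...) {
  cat("Five-parameter Rrs model coefficients (4 bands)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a coefficient set to JSON
#'
#' Serialises an `rrs_coefficients` object as a JSON object with one block
#' per band, each block holding the backscattering (C, B, D),
#' phytoplankton (G, F, H), non-algal (K, J, L) and CDOM (M, N, P)
#' constants plus `a_w`, `b_bw` and `f_over_q`. The file round-trips
#' losslessly through [read_coefficients()].
#'
#' @param coeffs An `rrs_coefficients` object (all four bands required).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coeffs, path) {
  if (!inherits(coeffs, "rrs_coefficients")) coeffs <- rrs_coefficients(coeffs)
  blocks <- lapply(seq_len(nrow(coeffs)), function(i) {
    as.list(coeffs[i, setdiff(names(coeffs), "band")])
  })
  names(blocks) <- as.character(coeffs$band)
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a coefficient set from JSON
#'
#' @param path JSON file written by [write_coefficients()] (or following
#'   the same schema: top-level keys "420", "488", "555", "620", each a
#'   block of named constants).
#' @return An `rrs_coefficients` object.
#' @export
read_coefficients <- function(path) {
  blocks <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!setequal(names(blocks), as.character(rrs_bands()))) {
    stop("coefficient file must contain exactly the four band blocks ",
         paste(rrs_bands(), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(names(blocks), function(b) {
    c(list(band = as.integer(b)), blocks[[b]])
  })
  rrs_coefficients(do.call(rbind, lapply(rows, as.data.frame)))
}
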