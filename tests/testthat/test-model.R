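test_that("one-parameter component models reproduce their published power laws", {
  cases <- rbind(
    data.frame(fn = "aph", x = 1, band = 420, want = 0.056),
    data.frame(fn = "aph", x = 0, band = 488, want = 0),
    data.frame(fn = "aph", x = 10, band = 488, want = 0.037 * 10^0.820),
    data.frame(fn = "ad", x = 1, band = 555, want = 0.031),
    data.frame(fn = "ad", x = 0, band = 420, want = 0),
    data.frame(fn = "ad", x = 5, band = 420, want = 0.071 * 5^0.809),
    data.frame(fn = "bbp", x = 1, band = 488, want = 0.008),
    data.frame(fn = "bbp", x = 0, band = 555, want = 0),
    data.frame(fn = "bbp", x = 10, band = 620, want = 0.005 * 10^0.881)
  )
  fns <- list(aph = aph_one_param, ad = ad_one_param, bbp = bbp_one_param)
  for (i in seq_len(nrow(cases))) {
    got <- fns[[cases$fn[i]]](cases$x[i], cases$band[i])
    expect_equal(got, cases$want[i], tolerance = 1e-12,
                 label = sprintf("%s(%g, %d)", cases$fn[i], cases$x[i],
                                 cases$band[i]))
  }
  expect_error(aph_one_param(-1, 420), "finite and >= 0")
  expect_error(ad_one_param(-0.1, 488), "finite and >= 0")
  expect_error(bbp_one_param(1, 500), "not a model band")
})

test_that("CDOM log-polynomial model matches hand evaluation and vanishes at zero", {
  # u = log10(a400) = 0 at a400 = 1, so the value is 10^(-P)
  expect_equal(acdom_model(1, 420), 10^(-0.132), tolerance = 1e-12)
  expect_equal(acdom_model(1, 488), 10^(-0.485), tolerance = 1e-12)
  expect_equal(acdom_model(0, 488), 0)
  expect_equal(acdom_model(c(0, 1), 555), c(0, 10^(-0.689)),
               tolerance = 1e-12)
  # absorption must decrease away from the 400 nm reference
  expect_lt(acdom_model(1, 420), 1)
  expect_error(acdom_model(-1, 420), "finite and >= 0")
})

test_that("two-parameter models apply the exponential composition correction", {
  expect_equal(aph_two_param(1, 0, 488), 0.022, tolerance = 1e-12)
  expect_equal(aph_two_param(1, 1, 488), 0.022 * exp(0.824),
               tolerance = 1e-12)
  expect_equal(aph_two_param(0, 0, 420), 0)
  expect_equal(ad_two_param(1, 0, 420), 0.057, tolerance = 1e-12)
  expect_equal(ad_two_param(1, 1, 488), 0.035 * exp(0.903),
               tolerance = 1e-12)
  expect_equal(ad_two_param(0, 0, 555), 0)
  expect_equal(bbp_two_param(1, 0, 620), 0.004, tolerance = 1e-12)
  expect_equal(bbp_two_param(1, 1, 488), 0.006 * exp(0.827),
               tolerance = 1e-12)
  expect_equal(bbp_two_param(0, 0, 420), 0)
  expect_error(aph_two_param(0, 1, 488), "diverges")
  expect_error(ad_two_param(1, 2, 488), "must not exceed")
  expect_error(bbp_two_param(1, 1.5, 420), "must not exceed")
})

test_that("absorption and backscattering budgets are exact sums with pure-water floors", {
  cv0 <- constituents(0, 0, 0, 0, 0)
  expect_equal(a_total(cv0, 488), 0.0147)
  expect_equal(a_total(cv0, 620), 0.2755)
  expect_equal(bb_total(cv0, 420), 0.0023)
  expect_equal(bb_total(cv0, 620), 0.0004)
  cv <- constituents(1, 0, 1, 0, 1)
  expect_equal(a_total(cv, 488), 0.022 + 0.035 + 10^(-0.485) + 0.0147,
               tolerance = 1e-12)
  expect_equal(bb_total(constituents(0, 0, 1, 0, 0), 488),
               0.006 + 0.0012, tolerance = 1e-12)
  # additivity holds exactly for arbitrary valid inputs
  set.seed(7)
  for (i in 1:20) {
    spm <- runif(1, 0, 10)
    chl <- runif(1, 0, 20)
    cv <- constituents(chl, runif(1, 0, chl), spm, runif(1, 0, spm),
                       runif(1, 0, 3))
    for (band in rrs_bands()) {
      k <- default_coefficients()[match(band, rrs_bands()), ]
      parts <- aph_two_param(cv$chl_a, cv$sum_c, band) +
        ad_two_param(cv$spm, cv$spm_inorg, band) +
        acdom_model(cv$a_cdom_400, band) + k$a_w
      expect_identical(a_total(cv, band), parts)
      expect_identical(bb_total(cv, band),
                       bbp_two_param(cv$spm, cv$spm_inorg, band) + k$b_bw)
      expect_gte(a_total(cv, band), k$a_w)
      expect_gte(bb_total(cv, band), k$b_bw)
    }
  }
})

test_that("forward reflectance is bounded by f/Q and hits the clear-water value", {
  cv0 <- constituents(0, 0, 0, 0, 0)
  expect_equal(rrs_forward(cv0, 420), 0.07 * 0.0023 / (0.0045 + 0.0023),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:50) {
    spm <- runif(1, 0.01, 20)
    chl <- runif(1, 0.01, 50)
    cv <- constituents(chl, runif(1, 0, chl), spm, runif(1, 0, spm),
                       runif(1, 0.01, 5))
    for (band in rrs_bands()) {
      fq <- default_coefficients()$f_over_q[match(band, rrs_bands())]
      r <- rrs_forward(cv, band)
      expect_gt(r, 0)
      expect_lt(r, fq)
    }
  }
})

test_that("component models increase strictly in their primary driver", {
  xs <- c(0.05, 0.2, 1, 5, 20)
  for (band in rrs_bands()) {
    expect_true(all(diff(aph_one_param(xs, band)) > 0))
    expect_true(all(diff(ad_one_param(xs, band)) > 0))
    expect_true(all(diff(bbp_one_param(xs, band)) > 0))
    expect_true(all(diff(aph_two_param(xs, 0.3 * xs, band)) > 0))
    expect_true(all(diff(ad_two_param(xs, 0.4 * xs, band)) > 0))
    expect_true(all(diff(bbp_two_param(xs, 0.4 * xs, band)) > 0))
    # the CDOM quadratic is increasing over the observed coastal range
    # of a_cdom_400 (its vertex lies beyond ~2.4 m-1 at the red bands)
    acd <- acdom_model(c(0.3, 0.6, 1, 1.5, 2), band)
    expect_true(all(diff(acd) > 0))
  }
})

test_that("inorganic-fraction correction multiplies within [1, e^rate]", {
  k <- default_coefficients()
  for (band in rrs_bands()) {
    i <- match(band, k$band)
    base_ad <- ad_two_param(3, 0, band)
    base_bbp <- bbp_two_param(3, 0, band)
    for (f in c(0, 0.25, 0.5, 1)) {
      rad <- ad_two_param(3, 3 * f, band) / base_ad
      rbb <- bbp_two_param(3, 3 * f, band) / base_bbp
      expect_gte(rad, 1); expect_lte(rad, exp(k$L[i]) + 1e-12)
      expect_gte(rbb, 1); expect_lte(rbb, exp(k$D[i]) + 1e-12)
    }
    expect_equal(ad_two_param(3, 3, band) / base_ad, exp(k$L[i]),
                 tolerance = 1e-12)
  }
})

test_that("inverting the reflectance relation recovers f/Q to machine precision", {
  set.seed(5)
  for (i in 1:25) {
    spm <- runif(1, 0.05, 15)
    chl <- runif(1, 0.05, 40)
    cv <- constituents(chl, runif(1, 0, chl), spm, runif(1, 0, spm),
                       runif(1, 0.05, 4))
    for (band in rrs_bands()) {
      fq <- default_coefficients()$f_over_q[match(band, rrs_bands())]
      got <- f_over_q_empirical(rrs_forward(cv, band), a_total(cv, band),
                                bb_total(cv, band))
      expect_equal(got, fq, tolerance = 1e-12)
    }
  }
})

test_that("radiometric ratios and their domain errors behave", {
  expect_equal(rrs_from_radiometry(1, 100), 0.01)
  expect_equal(rrs_from_radiometry(0, 1), 0)
  expect_equal(rrs_from_radiometry(0.5, 40), 0.0125)
  expect_error(rrs_from_radiometry(1, 0), "must be > 0")
  expect_equal(q_factor(5, 1), 5)
  expect_equal(q_factor(4.2, 2), 2.1)
  expect_error(q_factor(1, 0), "must be > 0")
  expect_equal(f_over_q_empirical(0.01, 0.10, 0.01), 0.11)
  expect_equal(f_over_q_empirical(0, 0.5, 0.01), 0)
  expect_error(f_over_q_empirical(0.01, 0.1, 0), "must be > 0")
})

test_that("published two-parameter coefficients compose from the residual prefactor", {
  # dividing the one-parameter coefficient by the residual-ratio
  # prefactor must give the two-parameter coefficient (within 1%, the
  # precision of the printed constants): 0.037 / 1.692 ~ 0.022 at 488 nm
  expect_equal(0.037 / 1.692, 0.022, tolerance = 0.01)
})

test_that("nearest channel selection is deterministic with shorter-wavelength ties", {
  channels <- c(412, 443, 490, 510, 555, 670, 683)
  expect_equal(nearest_band(420, channels), 412)
  expect_equal(nearest_band(555, channels), 555)
  expect_equal(nearest_band(620, channels), 670)
  expect_equal(nearest_band(427.5, c(412, 443)), 412)  # tie -> shorter
  expect_error(nearest_band(420, numeric(0)), "non-empty")
})

test_that("constituent validation enforces the physical constraints", {
  expect_error(constituents(1, 1, 1, 2, 1), "must not exceed")
  expect_error(constituents(0, 1, 1, 0.5, 1), "requires")
  expect_error(constituents(-1, 0, 1, 0.5, 1), "finite and >= 0")
  cv <- constituents(c(1, 2), c(0.3, 0.5), c(2, 3), c(1, 1), c(0.5, 1))
  expect_s3_class(cv, "constituents")
  expect_equal(nrow(cv), 2)
})
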