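test_that("ratio_to_delta matches the defining arithmetic and rejects bad input", {
  expect_equal(ratio_to_delta(0.0112, 0.0112), 0)
  expect_equal(ratio_to_delta(1.01 * 0.0112, 0.0112), 10)
  expect_equal(ratio_to_delta(0.98993, 1), -10.07)
  expect_error(ratio_to_delta(-1, 0.0112), "positive")
  expect_error(ratio_to_delta(0.0112, 0), "positive")
})

test_that("discrimination and its inverse agree with hand arithmetic", {
  expect_equal(discrimination(0, 0), 0)
  expect_equal(discrimination(-8.5, -30.07), 22.239, tolerance = 1e-4)
  expect_equal(discrimination(-8.5, -13.72), 5.293, tolerance = 1e-4)
  expect_error(discrimination(-8.5, -1000), "-1000")
  # inverse round-trips through arbitrary leaf values
  dp <- seq(-35, -10, by = 2.5)
  expect_equal(d13c_from_discrimination(-8.5, discrimination(-8.5, dp)), dp)
})

test_that("barometric pressure is the standard-atmosphere profile", {
  expect_identical(barometric_pressure(0), 101325)
  expect_equal(barometric_pressure(3800) / 1000, 63.3, tolerance = 1e-3)
  z <- seq(0, 4000, by = 250)
  expect_true(all(diff(barometric_pressure(z)) < 0))
  expect_error(barometric_pressure(-1000), "-500")
})

test_that("gamma_star collapses to Gamma*25 at reference conditions and scales with pressure", {
  k <- iwue_constants()
  expect_identical(gamma_star(298, k$p0), k$gamma_star_25)
  expect_equal(gamma_star(308, k$p0), 70.2, tolerance = 1e-3)
  expect_equal(gamma_star(290, k$p0 / 2), gamma_star(290, k$p0) / 2)
  expect_error(gamma_star(-5, k$p0), "positive")
})

test_that("simple C3 inversion hits its boundary cases and the worked value", {
  k <- iwue_constants()
  expect_equal(ci_simple_c3(k$a, 415), 0)
  expect_equal(ci_simple_c3(k$b, 415), 415)
  expect_equal(ci_simple_c3(22.239, 415), 300.96, tolerance = 1e-4)
  expect_error(ci_simple_c3(20, 415, iwue_constants(b = 4.4)), "Degenerate")
})

test_that("photorespiration term vanishes in the appropriate limits", {
  gs <- gamma_star(288, barometric_pressure(1500))
  p_ca <- 415e-6 * barometric_pressure(1500)
  no_f <- iwue_constants(f_prime = 0)
  expect_equal(ci_photoresp_c3(18, 415, gs, p_ca, no_f),
               ci_simple_c3(18, 415, no_f))
  expect_equal(ci_photoresp_c3(18, 415, 0, p_ca), ci_simple_c3(18, 415))
  expect_error(ci_photoresp_c3(18, 415, gs, -1), "positive")
})

test_that("mesophyll formulation collapses to photoresp as gsc/gm -> 0 and keeps Cc below its Ci", {
  gs <- gamma_star(288, barometric_pressure(1500))
  p_ca <- 415e-6 * barometric_pressure(1500)
  k0 <- iwue_constants(gsc_over_gm = 0)
  expect_equal(as.numeric(cc_mesophyll_c3(18, 415, gs, p_ca, k0)),
               ci_photoresp_c3(18, 415, gs, p_ca, k0))
  cc <- cc_mesophyll_c3(18, 415, gs, p_ca)
  expect_lt(as.numeric(cc), attr(cc, "ci_ppm"))
})

test_that("C4 inversion matches the printed-constant arithmetic and boundary behaviour", {
  k <- iwue_constants()
  expect_equal(ci_c4(k$a, 415), 0)
  expect_equal(delta_c4(415, 415), 0.222)
  expect_equal(ci_c4(3.0, 415), 139.1, tolerance = 1e-3)
  # zero slope is degenerate: phi chosen so b4 + (b3 - s) phi = a
  k_bad <- iwue_constants(phi = (4.4 + 5.7) / (30 - 1.8))
  expect_error(ci_c4(3, 415, k_bad), "Degenerate")
})

test_that("iWUE is the scaled Ca - Ci difference, decreasing in Ci", {
  expect_equal(iwue(415, 415), 0)
  expect_equal(iwue(415, 0), 259.375)
  expect_equal(iwue(415, 300.96), 71.3, tolerance = 1e-3)
  ci <- seq(10, 400, by = 10)
  expect_true(all(diff(iwue(415, ci)) < 0))
  expect_equal(ci_from_iwue(415, iwue(415, ci)), ci)
})

test_that("compute_iwue composes the chain and preserves row order", {
  tbl <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4),
    d13c_leaf = c(-30.07, -27, -25.5, -28.2),
    pathway = "C3",
    elevation_m = c(40, 900, 2500, 3700),
    mat_c = c(23, 18, 12, 8)
  )
  out <- compute_iwue(tbl, formulation = "simple")
  manual <- iwue(415, ci_simple_c3(discrimination(-8.5, tbl$d13c_leaf), 415))
  expect_equal(out$iwue, manual)
  expect_identical(out$sample_id, tbl$sample_id)
  expect_true(all(out$in_range))
  expect_identical(unique(out$formulation), "simple")
})

test_that("C4 samples at the C3-like mean leaf value are flagged out of range", {
  tbl <- tibble::tibble(d13c_leaf = -13.72, pathway = "C4",
                        elevation_m = 1000, mat_c = 15)
  expect_warning(out <- compute_iwue(tbl), "outside \\[0, 1\\]")
  expect_false(out$in_range)
  # discrimination 5.29 permil exceeds the model's valid [0.222, 4.4] band
  expect_gt(out$delta13c, 4.4)
  expect_lt(out$ci_over_ca, 0)
  expect_warning(
    dropped <- compute_iwue(tbl, drop_out_of_range = TRUE), "dropped"
  )
  expect_identical(nrow(dropped), 0L)
})

test_that("pathway/formulation mismatch and schema gaps are configuration errors", {
  tbl <- tibble::tibble(d13c_leaf = -28, pathway = "C3",
                        elevation_m = 100, mat_c = 20)
  expect_error(compute_iwue(tbl, formulation = "c4"), "incompatible")
  expect_error(compute_iwue(dplyr::select(tbl, -elevation_m)), "elevation_m")
  expect_error(
    compute_iwue(dplyr::select(tbl, -mat_c), formulation = "photoresp"),
    "mat_c"
  )
  # an implausibly enriched leaf warns about plausibility and, because the
  # implied discrimination is negative, also about the Ci/Ca range
  expect_warning(
    expect_warning(
      compute_iwue(tibble::tibble(d13c_leaf = -3, pathway = "C3",
                                  elevation_m = 0, mat_c = 20)),
      "plausible"
    ),
    "outside"
  )
})

test_that("the printed photorespiration sign is available as a switch", {
  gs <- gamma_star(293, barometric_pressure(500))
  p_ca <- 415e-6 * barometric_pressure(500)
  k <- iwue_constants()
  ci_model <- ci_photoresp_c3(18, 415, gs, p_ca, k, "model")
  ci_printed <- ci_photoresp_c3(18, 415, gs, p_ca, k, "printed")
  term <- k$f_prime * gs / 415
  expect_equal(ci_model - ci_printed, 415 * 2 * term / (k$b - k$a))
  # each convention round-trips with its own forward model
  for (sgn in c("model", "printed")) {
    fwd <- delta_photoresp_c3(250, 415, gs, p_ca, k, sgn)
    expect_equal(ci_photoresp_c3(fwd, 415, gs, p_ca, k, sgn), 250)
  }
})
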