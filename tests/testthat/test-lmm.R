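test_that("variance-component R-squared matches the hand oracle and its bounds", {
  expect_equal(unname(r2_components(2, 1, 1)), c(0.5, 0.75))
  expect_equal(unname(r2_components(0, 1, 3)), c(0, 0.25))
  r2 <- r2_components(1.3, 0.4, 2.1)
  expect_lte(r2[["r2_marginal"]], r2[["r2_conditional"]])
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_error(r2_components(0, 0, 0), "undefined")
  expect_error(r2_components(-1, 1, 1), ">= 0")
})

test_that("zero species variance gives a singular fit with matching marginal and conditional R2", {
  sim <- simulate_transect(transect_config(seed = 6, species_sd = 0))
  tbl <- compute_iwue(sim$data)
  expect_warning(
    fit <- fit_trend_lmm(dplyr::filter(tbl, pathway == "C3")),
    "Singular"
  )
  expect_lt(fit$sigma2_group, 1e-8)
  expect_equal(fit$r2_marginal, fit$r2_conditional, tolerance = 1e-6)
  # with the group variance at zero the fit collapses to least squares
  ols <- stats::lm(iwue ~ elevation_km,
                   data = dplyr::filter(tbl, pathway == "C3") |>
                     dplyr::mutate(elevation_km = elevation_m / 1000))
  expect_equal(tidy(fit)$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("duplicating every observation leaves the coefficient estimates unchanged", {
  sim <- simulate_transect(tiny_config(seed = 5))
  tbl <- dplyr::filter(compute_iwue(sim$data), pathway == "C3")
  f1 <- fit_trend_lmm(tbl)
  f2 <- fit_trend_lmm(dplyr::bind_rows(tbl, tbl))
  # REML variance components shift slightly under duplication, so the
  # generalised-least-squares weighting (and with it the point estimates)
  # is invariant only up to that re-weighting
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 0.02)
  expect_identical(f2$n_obs, 2L * f1$n_obs)
})

test_that("trend fits recover the configured pathway divergence on synthetic data", {
  sim <- simulate_transect(transect_config(seed = 21))
  tbl <- compute_iwue(sim$data)
  fits <- fit_pathway_trends(tbl)
  sl3 <- tidy(fits$C3)[2, ]
  sl4 <- tidy(fits$C4)[2, ]
  expect_gt(sl3$estimate, 0); expect_lt(sl3$p_value, 0.05)
  expect_lt(sl4$estimate, 0); expect_lt(sl4$p_value, 0.05)
  for (f in fits) {
    g <- glance(f)
    expect_gte(g$r2_conditional, g$r2_marginal)
    expect_equal(unname(r2_nakagawa(f)),
                 c(g$r2_marginal, g$r2_conditional))
  }
})

test_that("missing data are removed listwise with a message and the fit proceeds", {
  sim <- simulate_transect(tiny_config(seed = 7))
  tbl <- dplyr::filter(compute_iwue(sim$data), pathway == "C3")
  tbl$iwue[c(2, 9)] <- NA
  expect_message(fit <- fit_trend_lmm(tbl), "2 row")
  expect_identical(fit$n_obs, nrow(tbl) - 2L)
})

test_that("fit preconditions are enforced", {
  sim <- simulate_transect(tiny_config(seed = 2))
  tbl <- compute_iwue(sim$data)
  expect_error(fit_trend_lmm(tbl[1:5, ]), "at least 10")
  one_sp <- dplyr::filter(tbl, species_id == tbl$species_id[1])
  if (nrow(one_sp) >= 10) {
    expect_error(fit_trend_lmm(one_sp), "2 levels")
  }
  expect_error(fit_trend_lmm(tbl, response = "nope"), "nope")
})

test_that("tidy and glance expose the broom-style views", {
  sim <- simulate_transect(tiny_config(seed = 10))
  fit <- fit_trend_lmm(dplyr::filter(compute_iwue(sim$data),
                                     pathway == "C3"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "df", "statistic",
                     "p_value", "conf_low", "conf_high"))
  expect_identical(nrow(td), 2L)
  expect_true(all(td$conf_low < td$estimate & td$estimate < td$conf_high))
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})
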