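test_that("VIF equals the 1/(1 - R2) oracle on constructed correlations", {
  q <- orthonormal_basis(40, 3)
  x <- data.frame(
    x1 = q[, 1],
    x2 = 0.8 * q[, 1] + sqrt(1 - 0.64) * q[, 2], # exact sample r = 0.8
    x3 = q[, 3]
  )
  v <- vif(x)
  expect_equal(unname(v[c("x1", "x2")]), rep(1 / (1 - 0.64), 2),
               tolerance = 1e-8)
  expect_equal(unname(v["x3"]), 1, tolerance = 1e-8)
  # orthogonal pair: both VIFs exactly 1
  v2 <- vif(data.frame(a = q[, 1], b = q[, 2]))
  expect_equal(unname(v2), c(1, 1), tolerance = 1e-10)
  expect_error(vif(data.frame(a = 1:3)), "2 features")
  expect_error(vif(data.frame(a = 1:3, b = 3:1, c = c(1, 5, 2), d = 0:2)),
               "more observations")
})

test_that("the screen drops an exact duplicate and retains only sub-threshold features", {
  q <- orthonormal_basis(60, 3, seed = 7)
  x <- data.frame(a = q[, 1], b = q[, 2], c = q[, 3])
  x$a_copy <- x$a
  expect_message(scr <- vif_screen(x), "exact collinearity")
  expect_length(scr$dropped, 1)
  expect_true(scr$dropped %in% c("a", "a_copy"))
  expect_true(all(scr$vif < 10))
  expect_setequal(c(scr$retained, scr$dropped), names(x))
})

test_that("screening is invariant to the column order of the feature table", {
  sites <- generate_sites(transect_config(seed = 13))
  feats <- sites[c("elevation_m", "mat_c", "map_mm", "vpd_kpa", "ai",
                   "soil_soc", "soil_stn", "soil_cn")]
  s1 <- vif_screen(feats)
  s2 <- vif_screen(feats[, sample(ncol(feats))])
  expect_setequal(s1$retained, s2$retained)
  expect_identical(s1$dropped, s2$dropped)
})

test_that("a single noise-free driver is ranked first with the right sign", {
  d <- single_driver_data(noise_sd = 0, seed = 3)
  res <- fit_attribution(d, features = c("a", "b", "c", "d", "e"),
                         response = "y", seed = 3)
  imp <- tidy(res)
  expect_identical(imp$feature[1], "a")
  expect_identical(imp$dependence_sign[imp$feature == "a"], 1)
  expect_gt(imp$importance[1], 10 * imp$importance[2])
})

test_that("SHAP values are additive and the fit is reproducible under its seed", {
  d <- single_driver_data(seed = 4)
  r1 <- fit_attribution(d, features = letters[1:5], response = "y", seed = 9)
  r2 <- fit_attribution(d, features = letters[1:5], response = "y", seed = 9)
  expect_equal(rowSums(r1$shap) + r1$baseline, r1$prediction,
               tolerance = 1e-4)
  expect_identical(r1$importance, r2$importance)
  expect_error(
    fit_attribution(dplyr::mutate(d, y = 1), features = letters[1:5],
                    response = "y"),
    "constant"
  )
})

test_that("rank_report orders, truncates and writes deterministically", {
  d <- single_driver_data(seed = 6)
  res <- fit_attribution(d, features = letters[1:5], response = "y", seed = 2)
  full <- rank_report(res, top_k = 99)
  expect_identical(nrow(full$importance), 5L)
  expect_true(all(diff(full$importance$importance) <= 0))
  top2 <- rank_report(res, top_k = 2)
  expect_identical(nrow(top2$importance), 2L)
  dir <- withr::local_tempdir()
  rank_report(res, dir = dir)
  expect_true(file.exists(file.path(dir, "importance.csv")))
  expect_true(file.exists(file.path(dir, "dependence.csv")))
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("on the default synthetic transect VPD drives iWUE with opposite signs per pathway", {
  sim <- simulate_transect(transect_config(seed = 31))
  tbl <- compute_iwue(sim$data)
  signs <- purrr::map_dbl(c(C3 = "C3", C4 = "C4"), function(p) {
    res <- fit_attribution(dplyr::filter(tbl, pathway == p), seed = 31)
    imp <- tidy(res)
    expect_true("vpd_kpa" %in% imp$feature) # VPD survives the screen
    imp$dependence_sign[imp$feature == "vpd_kpa"]
  })
  truth <- sim$truth$attribution_signs
  expect_identical(unname(signs["C3"]), truth$sign[truth$pathway == "C3"])
  expect_identical(unname(signs["C4"]), truth$sign[truth$pathway == "C4"])
})
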