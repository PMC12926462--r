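test_that("default configuration yields 98 sites with climate inside the study envelopes", {
  for (s in c(3, 17)) {
    sites <- generate_sites(transect_config(seed = s))
    expect_identical(nrow(sites), 98L)
    expect_true(all(sites$elevation_m >= 40 & sites$elevation_m <= 3800))
    expect_true(all(sites$mat_c >= 7.6 & sites$mat_c <= 23.6))
    expect_true(all(sites$map_mm >= 730 & sites$map_mm <= 1760))
    expect_true(all(sites$vpd_kpa >= 0.2 & sites$vpd_kpa <= 1.3))
    expect_true(all(sites$ai >= 0.4 & sites$ai <= 1.7))
    # configured directions: MAT and VPD fall, MAP and AI rise
    expect_lt(cor(sites$elevation_m, sites$mat_c), -0.8)
    expect_lt(cor(sites$elevation_m, sites$vpd_kpa), -0.8)
    expect_gt(cor(sites$elevation_m, sites$ai), 0.8)
    expect_gt(cor(sites$elevation_m, sites$map_mm), 0.8)
  }
})

test_that("the generator is bit-identical under a repeated seed", {
  a <- simulate_transect(tiny_config(seed = 8))
  b <- simulate_transect(tiny_config(seed = 8))
  expect_identical(a$data, b$data)
  expect_identical(a$abundance, b$abundance)
  c <- simulate_transect(tiny_config(seed = 9))
  expect_false(identical(a$data$d13c_leaf, c$data$d13c_leaf))
})

test_that("zero climate noise makes the covariates exactly collinear with elevation", {
  sites <- generate_sites(noiseless_config())
  for (v in c("mat_c", "map_mm", "vpd_kpa", "ai")) {
    expect_equal(abs(cor(sites$elevation_m, sites[[v]])), 1)
  }
})

test_that("at zero noise compute_iwue recovers the true iWUE through the full chain", {
  for (form in c("simple", "photoresp", "mesophyll")) {
    sim <- simulate_transect(noiseless_config(formulation = form))
    out <- compute_iwue(sim$data, formulation = form)
    expect_equal(out$iwue, out$iwue_true, tolerance = 1e-9)
    expect_true(all(out$in_range))
  }
})

test_that("leaf delta-18O follows a hump with its peak inside the transect", {
  sim <- simulate_transect(transect_config(seed = 4))
  fit <- stats::lm(d18o_leaf ~ elevation_m + I(elevation_m^2),
                   data = sim$data)
  b <- stats::coef(fit)
  expect_lt(b[3], 0)
  peak <- -b[2] / (2 * b[3])
  expect_gt(peak, 40); expect_lt(peak, 3800)
})

test_that("the assembled table carries the full schema and conserves sample counts", {
  sim <- simulate_transect(tiny_config(seed = 6))
  schema_cols <- transect_schema()$column
  expect_true(all(schema_cols %in% names(sim$data)))
  expect_equal(nrow(sim$data),
               nrow(sim$dominants) * sim$config$n_replicates)
  expect_true(all(sim$data$site_id %in% sim$sites$site_id))
  expect_setequal(unique(sim$data$pathway), c("C3", "C4"))
  # key misalignment is a join error
  bad <- dplyr::mutate(sim$data, site_id = paste0("X", site_id))
  expect_error(assemble_transect(sim$sites, bad,
                                 list(abundance = sim$abundance,
                                      dominants = sim$dominants)),
               "align")
})

test_that("written transect files are identical across reruns of one seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_transect(simulate_transect(tiny_config(seed = 12)), d1)
  write_transect(simulate_transect(tiny_config(seed = 12)), d2)
  for (f in c("transect.csv", "ground_truth.csv")) {
    expect_identical(rlang::hash_file(file.path(d1, f))[[1]],
                     rlang::hash_file(file.path(d2, f))[[1]])
  }
})

test_that("configuration validation rejects degenerate transects", {
  expect_error(transect_config(n_sites = 1), "at least 2")
  expect_error(transect_config(elevation_range = c(3800, 40)), "increasing")
})
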