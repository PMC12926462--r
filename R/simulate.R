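#' Configuration for the synthetic elevational transect generator
#'
#' Collects every parameter of the generator: transect layout, climate
#' envelopes, species pools, the true iWUE model, and observation noise.
#' Defaults emulate a ~1000 km grassland transect: 98 sites between 40 and
#' 3800 m a.s.l. with MAT 7.6-23.6 degrees C, MAP 730-1760 mm, VPD 0.2-1.3
#' kPa and aridity index 0.4-1.7 co-varying with elevation; a positive
#' elevational iWUE trend for C3 grasses and a weak negative one for C4
#' grasses; species-level random intercepts; a hump-shaped leaf delta-18O
#' profile; and leaf/soil stoichiometry drifting with elevation.
#'
#' Climate noise is uniform with half-width `climate_noise_frac` times the
#' printed span, so generated marginals are guaranteed to stay inside the
#' stated envelopes for every seed while leaving enough independent
#' variation for collinearity screening to be meaningful.
#'
#' The true per-sample iWUE is
#' `intercept + slope * (z - z_min)/1000 + beta_vpd * (VPD - E[VPD|z]) +
#' species effect + residual`, so `true_slope_*` is the total elevational
#' trend (the quantity a mixed model of iWUE on elevation estimates) and
#' `beta_vpd_*` is a direct vapour-pressure-deficit effect with the
#' pathway-specific sign (negative for C3, positive for C4).
#'
#' @param n_sites Number of sites (default 98).
#' @param elevation_range Transect elevation span in m (default 40-3800).
#' @param n_species_c3,n_species_c4 Species pool sizes per pathway.
#' @param prob_c4 Probability that a dominant-species slot is C4.
#' @param dominants_range Range of dominant species per site (default 1-3).
#' @param n_replicates Leaf replicates per dominant species (default 3).
#' @param species_sd SD of species random intercepts, iWUE units.
#' @param residual_sd Residual SD of true iWUE, iWUE units.
#' @param intercept_c3,intercept_c4 Expected iWUE at the transect base,
#'   micromol CO2 / mol H2O.
#' @param true_slope_c3,true_slope_c4 Total elevational iWUE trend per
#'   1000 m.
#' @param beta_vpd_c3,beta_vpd_c4 Direct iWUE response to the VPD anomaly,
#'   per kPa.
#' @param mat_range,map_range,vpd_range,ai_range Climate envelopes
#'   (degrees C, mm, kPa, dimensionless). MAT and VPD decrease with
#'   elevation; MAP and AI increase.
#' @param climate_noise_frac Half-width of the uniform climate noise as a
#'   fraction of each envelope's span (default 0.16).
#' @param d18o_coef Quadratic coefficients `c(c0, c1, c2)` of the leaf
#'   delta-18O vs elevation (m) profile; the default peaks at 1800 m.
#' @param d18o_sd Sample-level delta-18O noise SD, permil.
#' @param formulation C3 formulation used to translate true iWUE into leaf
#'   delta-13C (and expected back out by [compute_iwue()]).
#' @param ca_ppm,d13c_air Atmospheric CO2 mole fraction (ppm) and air
#'   delta-13C (permil) assumed by the generator.
#' @param constants An [iwue_constants()] registry.
#' @param seed Integer master seed; every stage derives its stream from it.
#'
#' @return A list of class `transect_config`.
#' @export
transect_config <- function(n_sites = 98,
                            elevation_range = c(40, 3800),
                            n_species_c3 = 12, n_species_c4 = 8,
                            prob_c4 = 0.35,
                            dominants_range = c(1, 3),
                            n_replicates = 3,
                            species_sd = 8, residual_sd = 6,
                            intercept_c3 = 65, intercept_c4 = 150,
                            true_slope_c3 = 20, true_slope_c4 = -5,
                            beta_vpd_c3 = -15, beta_vpd_c4 = 15,
                            mat_range = c(7.6, 23.6),
                            map_range = c(730, 1760),
                            vpd_range = c(0.2, 1.3),
                            ai_range = c(0.4, 1.7),
                            climate_noise_frac = 0.16,
                            d18o_coef = c(24, 7.2e-3, -2e-6),
                            d18o_sd = 1.5,
                            formulation = c("simple", "photoresp", "mesophyll"),
                            ca_ppm = 415, d13c_air = -8.5,
                            constants = iwue_constants(),
                            seed = 1L) {
  if (n_sites < 2) stop("`n_sites` must be at least 2.", call. = FALSE)
  if (diff(elevation_range) <= 0) {
    stop("`elevation_range` must be increasing.", call. = FALSE)
  }
  structure(
    list(
      n_sites = n_sites, elevation_range = elevation_range,
      n_species_c3 = n_species_c3, n_species_c4 = n_species_c4,
      prob_c4 = prob_c4, dominants_range = dominants_range,
      n_replicates = n_replicates,
      species_sd = species_sd, residual_sd = residual_sd,
      intercept_c3 = intercept_c3, intercept_c4 = intercept_c4,
      true_slope_c3 = true_slope_c3, true_slope_c4 = true_slope_c4,
      beta_vpd_c3 = beta_vpd_c3, beta_vpd_c4 = beta_vpd_c4,
      mat_range = mat_range, map_range = map_range,
      vpd_range = vpd_range, ai_range = ai_range,
      climate_noise_frac = climate_noise_frac,
      d18o_coef = d18o_coef, d18o_sd = d18o_sd,
      formulation = match.arg(formulation),
      ca_ppm = ca_ppm, d13c_air = d13c_air,
      constants = constants, seed = as.integer(seed)
    ),
    class = "transect_config"
  )
}

# Seed hierarchy: each stage draws from seed + a fixed offset so the
# stages are individually reproducible and jointly deterministic.
stage_seed <- function(config, stage) {
  config$seed + switch(stage, sites = 0L, community = 1L, isotopes = 2L)
}

# Deterministic climate line: value at elevation z for an envelope
# c(lo, hi) with uniform noise half-width w = frac * span. The line runs
# from (lo + w) to (hi - w) so line + noise stays inside [lo, hi].
climate_line <- function(z, range, frac, increasing) {
  lo <- range[1]; hi <- range[2]
  w <- frac * (hi - lo)
  zr <- (z - min(z)) / diff(base::range(z))
  if (length(unique(z)) == 1) zr <- rep(0, length(z))
  if (increasing) (lo + w) + (hi - lo - 2 * w) * zr
  else (hi - w) - (hi - lo - 2 * w) * zr
}

climate_line_at <- function(z, elev_range, range, frac, increasing) {
  lo <- range[1]; hi <- range[2]
  w <- frac * (hi - lo)
  zr <- (z - elev_range[1]) / diff(elev_range)
  if (increasing) (lo + w) + (hi - lo - 2 * w) * zr
  else (hi - w) - (hi - lo - 2 * w) * zr
}

runif_pm <- function(n, w) if (w == 0) rep(0, n) else stats::runif(n, -w, w)

#' Generate transect sites with elevation-driven climate and soil
#'
#' Elevations are uniform over the configured range; MAT and VPD decrease
#' and MAP and AI increase linearly with elevation, each plus bounded
#' uniform noise, so the marginals stay inside the configured envelopes.
#' Soil organic carbon, total nitrogen and their ratio drift upward with
#' elevation.
#'
#' @param config A [transect_config()].
#' @return A tibble with one row per site: `site_id`, `elevation_m`,
#'   `mat_c`, `map_mm`, `vpd_kpa`, `ai`, `soil_soc`, `soil_stn`, `soil_cn`.
#' @export
generate_sites <- function(config = transect_config()) {
  cfg <- config
  withr::with_seed(stage_seed(cfg, "sites"), {
    n <- cfg$n_sites
    z <- sort(stats::runif(n, cfg$elevation_range[1], cfg$elevation_range[2]))
    frac <- cfg$climate_noise_frac
    lineat <- function(range, inc) {
      climate_line_at(z, cfg$elevation_range, range, frac, inc)
    }
    noise <- function(range) runif_pm(n, frac * diff(range))
    z_km <- z / 1000
    soil_cn <- 9 + 1.2 * z_km + runif_pm(n, 1.2)
    soil_soc <- 15 + 13 * z_km + runif_pm(n, 8)
    tibble::tibble(
      site_id = sprintf("S%03d", seq_len(n)),
      elevation_m = z,
      mat_c = lineat(cfg$mat_range, FALSE) + noise(cfg$mat_range),
      map_mm = lineat(cfg$map_range, TRUE) + noise(cfg$map_range),
      vpd_kpa = lineat(cfg$vpd_range, FALSE) + noise(cfg$vpd_range),
      ai = lineat(cfg$ai_range, TRUE) + noise(cfg$ai_range),
      soil_soc = soil_soc,
      soil_stn = soil_soc / soil_cn,
      soil_cn = soil_cn
    )
  })
}

#' Generate plot-level abundances and pick dominant species
#'
#' Each site carries six 1 m x 1 m plots. One to three dominant species are
#' drawn per site (pathway decided by `prob_c4`) and given the largest
#' abundances; a random complement of subordinate species fills the plots.
#'
#' @param sites Output of [generate_sites()].
#' @param config A [transect_config()].
#' @return A list with `abundance` (site_id, plot_id, species_id,
#'   abundance) and `dominants` (site_id, species_id, pathway, weight =
#'   relative site-pooled abundance among dominants).
#' @export
generate_community <- function(sites, config = transect_config()) {
  cfg <- config
  pool_c3 <- sprintf("C3_sp%02d", seq_len(cfg$n_species_c3))
  pool_c4 <- sprintf("C4_sp%02d", seq_len(cfg$n_species_c4))
  withr::with_seed(stage_seed(cfg, "community"), {
    per_site <- purrr::map(seq_len(nrow(sites)), function(i) {
      sid <- sites$site_id[i]
      n_dom <- sample(seq(cfg$dominants_range[1], cfg$dominants_range[2]), 1)
      path <- ifelse(stats::runif(n_dom) < cfg$prob_c4, "C4", "C3")
      dom <- character(n_dom)
      for (p in unique(path)) {
        pool <- if (p == "C4") pool_c4 else pool_c3
        dom[path == p] <- sample(pool, sum(path == p))
      }
      n_sub <- sample(3:8, 1)
      sub <- sample(setdiff(c(pool_c3, pool_c4), dom), n_sub)
      species <- c(dom, sub)
      ab <- purrr::map(1:6, function(plt) {
        present <- c(rep(TRUE, n_dom), stats::runif(n_sub) < 0.6)
        a <- numeric(length(species))
        a[seq_len(n_dom)] <- stats::rlnorm(n_dom, meanlog = 3, sdlog = 0.3)
        a[-seq_len(n_dom)] <- ifelse(present[-seq_len(n_dom)],
                                     stats::rlnorm(n_sub, 1.2, 0.5), 0)
        tibble::tibble(site_id = sid, plot_id = sprintf("%s_P%d", sid, plt),
                       species_id = species, abundance = a)
      }) |> purrr::list_rbind()
      dom_tot <- ab |>
        dplyr::filter(.data$species_id %in% dom) |>
        dplyr::group_by(.data$species_id) |>
        dplyr::summarise(total = sum(.data$abundance), .groups = "drop")
      dominants <- tibble::tibble(
        site_id = sid, species_id = dom_tot$species_id,
        pathway = ifelse(dom_tot$species_id %in% pool_c4, "C4", "C3"),
        weight = dom_tot$total / sum(dom_tot$total)
      )
      list(abundance = ab, dominants = dominants)
    })
    list(
      abundance = purrr::list_rbind(purrr::map(per_site, "abundance")),
      dominants = purrr::list_rbind(purrr::map(per_site, "dominants"))
    )
  })
}

#' Simulate leaf isotope and stoichiometry samples
#'
#' For every dominant species at every site, `n_replicates` leaves are
#' simulated. A true iWUE is drawn from the configured elevational model
#' (intercept + slope + VPD anomaly effect + species intercept + residual),
#' converted to Ci via the inverse of the iWUE definition, pushed through
#' the pathway's forward discrimination model, and expressed as leaf
#' delta-13C. Draws implying Ci/Ca outside \[0, 1\] are resampled (new
#' residual) up to 100 times. Leaf delta-18O follows the quadratic
#' elevation profile; leaf C, N and P drift with elevation.
#'
#' @param sites Output of [generate_sites()].
#' @param dominants The `dominants` element of [generate_community()].
#' @param config A [transect_config()].
#' @return A list with `samples` (a tibble, one row per leaf) and `truth`
#'   (a `transect_truth` list: species effects, slopes, direct-effect
#'   coefficients and expected attribution signs).
#' @export
simulate_leaf_isotopes <- function(sites, dominants,
                                   config = transect_config()) {
  cfg <- config
  k <- cfg$constants
  withr::with_seed(stage_seed(cfg, "isotopes"), {
    species <- sort(unique(dominants$species_id))
    sp_eff <- tibble::tibble(
      species_id = species,
      pathway = ifelse(grepl("^C4", species), "C4", "C3"),
      intercept_dev = stats::rnorm(length(species), 0, cfg$species_sd)
    )
    long <- dominants |>
      dplyr::left_join(sites, by = "site_id") |>
      dplyr::left_join(sp_eff[, c("species_id", "intercept_dev")],
                       by = "species_id") |>
      tidyr::uncount(cfg$n_replicates, .id = "replicate")

    z_km <- (long$elevation_m - cfg$elevation_range[1]) / 1000
    vpd_line <- climate_line_at(long$elevation_m, cfg$elevation_range,
                                cfg$vpd_range, cfg$climate_noise_frac, FALSE)
    vpd_anom <- long$vpd_kpa - vpd_line
    is_c4 <- long$pathway == "C4"
    mu <- ifelse(is_c4,
                 cfg$intercept_c4 + cfg$true_slope_c4 * z_km +
                   cfg$beta_vpd_c4 * vpd_anom,
                 cfg$intercept_c3 + cfg$true_slope_c3 * z_km +
                   cfg$beta_vpd_c3 * vpd_anom) +
      long$intercept_dev

    n <- nrow(long)
    iwue_true <- mu + stats::rnorm(n, 0, cfg$residual_sd)
    ci_true <- ci_from_iwue(cfg$ca_ppm, iwue_true)
    bad <- ci_true < 0 | ci_true > cfg$ca_ppm
    tries <- 0
    while (any(bad) && tries < 100) {
      iwue_true[bad] <- mu[bad] + stats::rnorm(sum(bad), 0, cfg$residual_sd)
      ci_true <- ci_from_iwue(cfg$ca_ppm, iwue_true)
      bad <- ci_true < 0 | ci_true > cfg$ca_ppm
      tries <- tries + 1
    }
    if (any(bad)) {
      warning(sum(bad), " sample(s) remain outside the physical Ci range ",
              "after resampling; flagged.", call. = FALSE)
    }

    patm <- barometric_pressure(long$elevation_m, k)
    p_ca <- cfg$ca_ppm * 1e-6 * patm
    gs <- gamma_star(long$mat_c + 273.15, patm, k)
    delta <- numeric(n)
    delta[is_c4] <- delta_c4(ci_true[is_c4], cfg$ca_ppm, k)
    if (any(!is_c4)) {
      i <- !is_c4
      delta[i] <- switch(cfg$formulation,
        simple = delta_simple_c3(ci_true[i], cfg$ca_ppm, k),
        photoresp = delta_photoresp_c3(ci_true[i], cfg$ca_ppm, gs[i],
                                       p_ca[i], k),
        mesophyll = delta_mesophyll_c3(ci_true[i], cfg$ca_ppm, gs[i],
                                       p_ca[i], k)
      )
    }
    d13c_leaf <- d13c_from_discrimination(cfg$d13c_air, delta)

    c0 <- cfg$d18o_coef[1]; c1 <- cfg$d18o_coef[2]; c2 <- cfg$d18o_coef[3]
    d18o <- c0 + c1 * long$elevation_m + c2 * long$elevation_m^2 +
      stats::rnorm(n, 0, cfg$d18o_sd)

    leaf_c <- 430 + 8 * z_km + runif_pm(n, 15)
    leaf_n <- 22 - 1.5 * z_km + runif_pm(n, 4)
    leaf_p <- 1.9 - 0.25 * z_km + runif_pm(n, 0.35)

    samples <- tibble::tibble(
      sample_id = sprintf("%s_%s_r%d", long$site_id, long$species_id,
                          long$replicate),
      site_id = long$site_id,
      species_id = long$species_id,
      pathway = long$pathway,
      replicate = long$replicate,
      d13c_leaf = d13c_leaf,
      d18o_leaf = d18o,
      leaf_c = leaf_c, leaf_n = leaf_n, leaf_p = leaf_p,
      leaf_cn = leaf_c / leaf_n,
      leaf_np = leaf_n / leaf_p,
      leaf_cp = leaf_c / leaf_p,
      iwue_true = iwue_true,
      in_physical_range = !bad
    )

    truth <- structure(
      list(
        species_effects = sp_eff,
        true_slope_c3 = cfg$true_slope_c3,
        true_slope_c4 = cfg$true_slope_c4,
        beta_vpd_c3 = cfg$beta_vpd_c3,
        beta_vpd_c4 = cfg$beta_vpd_c4,
        attribution_signs = tibble::tibble(
          feature = rep("vpd_kpa", 2),
          pathway = c("C3", "C4"),
          sign = c(sign(cfg$beta_vpd_c3), sign(cfg$beta_vpd_c4))
        ),
        formulation = cfg$formulation,
        ca_ppm = cfg$ca_ppm, d13c_air = cfg$d13c_air,
        seed = cfg$seed
      ),
      class = "transect_truth"
    )
    list(samples = samples, truth = truth)
  })
}

#' Assemble the tidy transect table
#'
#' Joins samples to their site covariates, adds per-site diversity metrics
#' (species richness and Shannon index) and community-weighted means of
#' the leaf traits (weighted by dominant-species abundance), yielding the
#' one-row-per-leaf table consumed by the statistical stages.
#'
#' @param sites,samples,community Outputs of [generate_sites()],
#'   [simulate_leaf_isotopes()] and [generate_community()].
#' @return A tibble matching the transect CSV schema (see
#'   [transect_schema()]), plus the generator-only columns `iwue_true` and
#'   `in_physical_range`.
#' @export
assemble_transect <- function(sites, samples, community) {
  if (!all(samples$site_id %in% sites$site_id)) {
    stop("Sample/site keys do not align.", call. = FALSE)
  }
  metrics <- site_community_metrics(community$abundance)
  sp_traits <- samples |>
    dplyr::group_by(.data$site_id, .data$species_id) |>
    dplyr::summarise(dplyr::across(c("leaf_c", "leaf_n", "leaf_p"), mean),
                     .groups = "drop")
  cwm <- community$dominants |>
    dplyr::left_join(sp_traits, by = c("site_id", "species_id")) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      cwm_leaf_c = community_weighted_mean(.data$leaf_c, .data$weight),
      cwm_leaf_n = community_weighted_mean(.data$leaf_n, .data$weight),
      cwm_leaf_p = community_weighted_mean(.data$leaf_p, .data$weight),
      .groups = "drop"
    )
  samples |>
    dplyr::left_join(sites, by = "site_id") |>
    dplyr::left_join(metrics, by = "site_id") |>
    dplyr::left_join(cwm, by = "site_id")
}

#' Simulate a complete synthetic transect dataset
#'
#' Runs the full generator hierarchy (sites, community, leaf samples,
#' assembly) from the single seed in the configuration. Identical
#' configurations yield bit-identical outputs.
#'
#' @param config A [transect_config()].
#' @return A list of class `transect_sim`: `data` (the tidy transect
#'   table), `sites`, `abundance`, `dominants`, `truth`, `config`.
#' @examples
#' sim <- simulate_transect(transect_config(n_sites = 10, seed = 7))
#' dplyr::count(sim$data, pathway)
#' @export
simulate_transect <- function(config = transect_config()) {
  sites <- generate_sites(config)
  community <- generate_community(sites, config)
  iso <- simulate_leaf_isotopes(sites, community$dominants, config)
  data <- assemble_transect(sites, iso$samples, community)
  structure(
    list(data = data, sites = sites, abundance = community$abundance,
         dominants = community$dominants, truth = iso$truth, config = config),
    class = "transect_sim"
  )
}

#' Write a simulated transect to disk
#'
#' Writes `transect.csv`, `ground_truth.csv` (species effects plus the true
#' slopes and signs as attribute rows) and `config.json` (an echo of the
#' scalar configuration) into `dir`.
#'
#' @param sim A `transect_sim` from [simulate_transect()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_transect <- function(sim, dir) {
  stopifnot(inherits(sim, "transect_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$data, file.path(dir, "transect.csv"))
  truth_tbl <- sim$truth$species_effects |>
    dplyr::mutate(
      true_slope = ifelse(.data$pathway == "C4", sim$truth$true_slope_c4,
                          sim$truth$true_slope_c3),
      beta_vpd = ifelse(.data$pathway == "C4", sim$truth$beta_vpd_c4,
                        sim$truth$beta_vpd_c3)
    )
  readr::write_csv(truth_tbl, file.path(dir, "ground_truth.csv"))
  scalars <- sim$config[!vapply(sim$config, is.object, logical(1))]
  jsonlite::write_json(scalars, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
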