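#' Transect CSV column dictionary
#'
#' The tidy interchange schema: one row per leaf sample. Mandatory columns
#' identify the sample and carry the isotope measurement and elevation;
#' the remaining columns are covariates consumed by the statistical
#' stages.
#'
#' @return A tibble with columns `column`, `type`, `unit`, `required`.
#' @export
transect_schema <- function() {
  tibble::tribble(
    ~column,        ~type,       ~unit,                      ~required,
    "sample_id",    "character", "",                          TRUE,
    "site_id",      "character", "",                          TRUE,
    "species_id",   "character", "",                          TRUE,
    "pathway",      "character", "C3|C4",                     TRUE,
    "d13c_leaf",    "numeric",   "permil vs PDB",             TRUE,
    "elevation_m",  "numeric",   "m a.s.l.",                  TRUE,
    "d18o_leaf",    "numeric",   "permil vs SMOW",            FALSE,
    "mat_c",        "numeric",   "degree C",                  FALSE,
    "map_mm",       "numeric",   "mm/yr",                     FALSE,
    "vpd_kpa",      "numeric",   "kPa",                       FALSE,
    "ai",           "numeric",   "dimensionless",             FALSE,
    "leaf_c",       "numeric",   "mg/g",                      FALSE,
    "leaf_n",       "numeric",   "mg/g",                      FALSE,
    "leaf_p",       "numeric",   "mg/g",                      FALSE,
    "leaf_cn",      "numeric",   "ratio",                     FALSE,
    "leaf_np",      "numeric",   "ratio",                     FALSE,
    "leaf_cp",      "numeric",   "ratio",                     FALSE,
    "sr",           "numeric",   "species/plot",              FALSE,
    "shannon",      "numeric",   "nats",                      FALSE,
    "soil_soc",     "numeric",   "g/kg",                      FALSE,
    "soil_stn",     "numeric",   "g/kg",                      FALSE,
    "soil_cn",      "numeric",   "ratio",                     FALSE
  )
}

#' Validate a transect table against the schema
#'
#' Checks that every mandatory column is present and typed correctly, that
#' `pathway` holds only `"C3"`/`"C4"`, and that unit sanity bounds hold
#' (elevation in \[-500, 9000\] m, VPD in \[0, 20\] kPa, delta-13C in
#' \[-60, 20\] permil). Structural problems (missing columns) are errors;
#' value problems are collected into a row-level report.
#'
#' @param x A data frame or a path to a CSV file (UTF-8, header row).
#' @return The validated tibble, with a `problems` attribute: a tibble
#'   (`row`, `column`, `problem`) that has zero rows for a clean table.
#' @export
validate_transect <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("File not found: ", x, call. = FALSE)
    x <- readr::read_csv(x, show_col_types = FALSE)
  }
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  schema <- transect_schema()
  required <- schema$column[schema$required]
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("Schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- list()
  note <- function(rows, column, problem) {
    if (length(rows) > 0) {
      problems[[length(problems) + 1]] <<-
        tibble::tibble(row = rows, column = column, problem = problem)
    }
  }
  numeric_cols <- intersect(schema$column[schema$type == "numeric"], names(x))
  for (col in numeric_cols) {
    if (!is.numeric(x[[col]])) {
      coerced <- suppressWarnings(as.numeric(x[[col]]))
      note(which(is.na(coerced) & !is.na(x[[col]])), col, "non-numeric value")
      x[[col]] <- coerced
    }
  }
  note(which(!x$pathway %in% c("C3", "C4")), "pathway", "not C3/C4")
  bound <- function(col, lo, hi, unit) {
    if (col %in% names(x)) {
      note(which(!is.na(x[[col]]) & (x[[col]] < lo | x[[col]] > hi)),
           col, sprintf("outside [%g, %g] %s", lo, hi, unit))
    }
  }
  bound("elevation_m", -500, 9000, "m")
  bound("vpd_kpa", 0, 20, "kPa")
  bound("d13c_leaf", -60, 20, "permil")
  report <- if (length(problems) > 0) purrr::list_rbind(problems)
            else tibble::tibble(row = integer(), column = character(),
                                problem = character())
  if (nrow(report) > 0) {
    warning(nrow(report), " row-level validation problem(s); see ",
            "attr(, 'problems').", call. = FALSE)
  }
  attr(x, "problems") <- report
  x
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a transect table, compute iWUE, fit the per-pathway
#' elevational mixed models, run the driver attribution, and write every
#' stage artifact plus a manifest recording the inputs, seeds, constants
#' and content hashes, so a rerun with the same configuration is
#' verifiably identical.
#'
#' @param out_dir Output directory for the stage artifacts.
#' @param input Optional path to an existing transect CSV; when `NULL`
#'   (default) a synthetic transect is simulated from `config`.
#' @param config A [transect_config()] (also supplies constants, Ca and
#'   air delta-13C for the iWUE stage).
#' @param formulation C3 formulation for [compute_iwue()]; defaults to the
#'   generator's, so simulated data round-trips.
#' @param seed Overrides `config$seed` (and seeds the attribution stage).
#' @param stages Character vector choosing which stages run; earlier
#'   artifacts in `out_dir` are reused when a stage is toggled off.
#' @return A list with `data` (iWUE table), `fits`, `attribution` (per
#'   pathway), and `manifest`, invisibly; artifacts land in `out_dir`.
#' @export
run_pipeline <- function(out_dir, input = NULL, config = transect_config(),
                         formulation = NULL, seed = NULL,
                         stages = c("simulate", "iwue", "fit", "attribute")) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(formulation)) formulation <- config$formulation
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    message(msg)
    cat(msg, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
  }
  stage_failed <- function(stage, e) {
    stop("Pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # -- simulate / load -----------------------------------------------------
  transect_path <- file.path(out_dir, "transect.csv")
  if ("simulate" %in% stages && is.null(input)) {
    log_line("simulate: generating synthetic transect (seed ", config$seed, ")")
    sim <- tryCatch(simulate_transect(config),
                    error = function(e) stage_failed("simulate", e))
    write_transect(sim, out_dir)
    tbl <- sim$data
  } else {
    src <- if (!is.null(input)) input else transect_path
    log_line("load: reading ", src)
    tbl <- validate_transect(src)
  }
  tbl <- validate_transect(tbl)

  # -- iwue ----------------------------------------------------------------
  iwue_path <- file.path(out_dir, "iwue.csv")
  if ("iwue" %in% stages) {
    log_line("iwue: formulation '", formulation, "'")
    tbl <- tryCatch(
      compute_iwue(tbl, formulation = formulation,
                   constants = config$constants,
                   ca_ppm = config$ca_ppm, d13c_air = config$d13c_air),
      error = function(e) stage_failed("iwue", e)
    )
    readr::write_csv(tbl, iwue_path)
  } else {
    tbl <- readr::read_csv(iwue_path, show_col_types = FALSE)
  }

  # -- fit -----------------------------------------------------------------
  fits <- NULL
  if ("fit" %in% stages) {
    log_line("fit: per-pathway elevational mixed models")
    fits <- tryCatch(fit_pathway_trends(tbl),
                     error = function(e) stage_failed("fit", e))
    fit_tbl <- purrr::imap(fits, function(f, p) {
      dplyr::mutate(tidy(f), pathway = p,
                    r2_marginal = f$r2_marginal,
                    r2_conditional = f$r2_conditional,
                    n_obs = f$n_obs, n_groups = f$n_groups)
    }) |> purrr::list_rbind()
    readr::write_csv(fit_tbl, file.path(out_dir, "fits.csv"))
  }

  # -- attribute -----------------------------------------------------------
  attribution <- NULL
  if ("attribute" %in% stages) {
    log_line("attribute: VIF screen + boosted trees + SHAP per pathway")
    attribution <- purrr::map(
      stats::setNames(nm = intersect(c("C3", "C4"), unique(tbl$pathway))),
      function(p) {
        res <- tryCatch(
          fit_attribution(dplyr::filter(tbl, .data$pathway == p),
                          seed = config$seed),
          error = function(e) stage_failed("attribute", e)
        )
        rank_report(res, dir = file.path(out_dir, paste0("attribution_", p)))
        res
      }
    )
  }

  # -- manifest ------------------------------------------------------------
  scalars <- config[!vapply(config, is.object, logical(1))]
  manifest <- list(
    created = "run",
    stages = stages,
    formulation = formulation,
    seed = config$seed,
    constants = unclass(config$constants),
    atmosphere = list(ca_ppm = config$ca_ppm, d13c_air = config$d13c_air),
    config = scalars,
    n_rows = nrow(tbl),
    hashes = list(
      transect = if (file.exists(transect_path))
        rlang::hash_file(transect_path)[[1]] else NA,
      iwue = if (file.exists(iwue_path))
        rlang::hash_file(iwue_path)[[1]] else NA
    ),
    versions = list(
      isowue = as.character(utils::packageVersion("isowue")),
      r = as.character(getRversion())
    ),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done in ", sprintf("%.1f s", manifest$elapsed_s))
  invisible(list(data = tbl, fits = fits, attribution = attribution,
                 manifest = manifest))
}

#' Mean leaf delta-13C by photosynthetic pathway
#'
#' Summary used to compare a field dataset against reported pathway-level
#' means (e.g. for replication against deposited field data).
#'
#' @param data A transect table (or path to one) with `pathway` and
#'   `d13c_leaf`.
#' @return A tibble with one row per pathway: n, mean, and SD of leaf
#'   delta-13C.
#' @export
summarise_d13c_by_pathway <- function(data) {
  if (is.character(data)) data <- validate_transect(data)
  data |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_d13c = mean(.data$d13c_leaf, na.rm = TRUE),
      sd_d13c = stats::sd(.data$d13c_leaf, na.rm = TRUE),
      .groups = "drop"
    )
}
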