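#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing feature `j`
#' on all the others. A feature that is an exact linear combination of the
#' others gets `VIF = Inf`.
#'
#' @param features A data frame of numeric candidate features (>= 2
#'   columns, more rows than columns).
#' @return A named numeric vector of VIFs.
#' @examples
#' vif(data.frame(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(features) {
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("Need at least 2 features.", call. = FALSE)
  if (nrow(features) <= ncol(features)) {
    stop("Need more observations than features.", call. = FALSE)
  }
  if (!all(vapply(features, is.numeric, logical(1)))) {
    stop("All features must be numeric.", call. = FALSE)
  }
  vapply(names(features), function(j) {
    # an exact linear combination triggers summary.lm's perfect-fit warning
    r2 <- suppressWarnings(summary(stats::lm(
      stats::reformulate(sprintf("`%s`", setdiff(names(features), j)),
                         response = sprintf("`%s`", j)),
      data = features
    )))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative collinearity screening by VIF
#'
#' Repeatedly computes VIFs and drops the single highest-VIF feature while
#' any VIF is at or above the threshold. Deterministic; ties broken
#' alphabetically; the result is independent of the column order of the
#' input.
#'
#' @inheritParams vif
#' @param threshold Retain only features with `VIF < threshold`
#'   (default 10).
#' @return A list of class `vif_screen`: `retained` (feature names, in the
#'   original order), `dropped` (in drop order), `vif` (final VIFs of the
#'   retained set), and `history` (a tibble of per-iteration VIFs).
#' @examples
#' x <- data.frame(a = rnorm(60), b = rnorm(60))
#' x$dup <- x$a
#' vif_screen(x)$dropped
#' @export
vif_screen <- function(features, threshold = 10) {
  features <- as.data.frame(features)
  current <- features[, sort(names(features)), drop = FALSE]
  dropped <- character(0)
  history <- list()
  iter <- 0L
  while (ncol(current) >= 2) {
    iter <- iter + 1L
    v <- vif(current)
    history[[iter]] <- tibble::tibble(
      iteration = iter, feature = names(v), vif = unname(v)
    )
    if (all(v < threshold)) break
    worst <- names(v)[which.max(v)] # names sorted, so ties go alphabetically
    if (is.infinite(max(v))) {
      message("Dropping `", worst, "` (infinite VIF: exact collinearity).")
    }
    dropped <- c(dropped, worst)
    current <- current[, setdiff(names(current), worst), drop = FALSE]
  }
  retained <- intersect(names(features), names(current))
  structure(
    list(
      retained = retained,
      dropped = dropped,
      vif = if (ncol(current) >= 2) vif(current[, sort(retained), drop = FALSE])
            else stats::setNames(1, retained),
      threshold = threshold,
      history = purrr::list_rbind(history)
    ),
    class = "vif_screen"
  )
}

#' @export
print.vif_screen <- function(x, ...) {
  cat("<vif_screen> threshold", x$threshold, "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped) > 0) {
    cat("  dropped: ", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

default_features <- c(
  "elevation_m", "mat_c", "map_mm", "vpd_kpa", "ai",
  "leaf_c", "leaf_n", "leaf_p", "leaf_cn", "leaf_np", "leaf_cp",
  "sr", "shannon", "soil_soc", "soil_stn", "soil_cn"
)

#' Driver attribution with gradient-boosted trees and SHAP
#'
#' Fits an XGBoost regression of the response on the retained features and
#' computes per-observation SHAP values (TreeSHAP). Feature importance is
#' the mean absolute SHAP value; the dependence "sign" of each feature is
#' the sign of the Spearman rank correlation between the feature values
#' and their SHAP values. Hyperparameters default to shallow trees with a
#' moderate learning rate and early stopping on a seeded 80/20 split, and
#' are all recorded in the result. Deterministic for a fixed seed
#' (single-threaded).
#'
#' @param data A data frame holding the response and features.
#' @param features Feature column names (default: the climate, plant and
#'   soil covariates of the transect schema that are present in `data`).
#' @param response Response column name (default `"iwue"`).
#' @param seed Integer seed for the split and the stochastic tree fitting.
#' @param screen If `TRUE` (default) run [vif_screen()] first and use only
#'   the retained features.
#' @param vif_threshold Threshold passed to [vif_screen()].
#' @param params XGBoost parameters (a list) overriding the defaults
#'   `max_depth = 3`, `eta = 0.1`, `subsample = 0.8`,
#'   `colsample_bytree = 0.8`, `min_child_weight = 3`.
#' @param nrounds Maximum boosting rounds (default 500).
#' @param early_stopping_rounds Early-stopping patience on the held-out
#'   fifth (default 25).
#' @return An object of class `iwue_attribution`: `importance` (a tibble
#'   sorted by mean |SHAP|, ties broken alphabetically, with the
#'   dependence sign and rank), `shap` (n x features matrix), `baseline`
#'   (the SHAP base value), `model`, `screen`, `params`, `seed`.
#' @export
fit_attribution <- function(data, features = NULL, response = "iwue",
                            seed = 1L, screen = TRUE, vif_threshold = 10,
                            params = list(), nrounds = 500,
                            early_stopping_rounds = 25) {
  stopifnot(is.data.frame(data))
  if (is.null(features)) {
    features <- intersect(default_features, names(data))
  }
  missing_cols <- setdiff(c(features, response), names(data))
  if (length(missing_cols) > 0) {
    stop("Missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[c(features, response)])
  data <- data[keep, ]
  y <- data[[response]]
  if (stats::sd(y) == 0) {
    stop("Response is constant; attribution is undefined.", call. = FALSE)
  }

  scr <- NULL
  if (screen) {
    scr <- vif_screen(data[features], threshold = vif_threshold)
    features <- scr$retained
  }
  if (length(features) == 0) stop("No features retained.", call. = FALSE)

  x <- as.matrix(data[features])
  defaults <- list(max_depth = 3, eta = 0.1, subsample = 0.8,
                   colsample_bytree = 0.8, min_child_weight = 3,
                   objective = "reg:squarederror", nthread = 1)
  params <- utils::modifyList(defaults, params)

  booster <- withr::with_seed(seed, {
    n <- nrow(x)
    idx_val <- sample.int(n, max(1, round(0.2 * n)))
    dtrain <- xgboost::xgb.DMatrix(x[-idx_val, , drop = FALSE],
                                   label = y[-idx_val])
    dval <- xgboost::xgb.DMatrix(x[idx_val, , drop = FALSE],
                                 label = y[idx_val])
    xgboost::xgb.train(
      params = params, data = dtrain, nrounds = nrounds,
      evals = list(val = dval),
      early_stopping_rounds = early_stopping_rounds, verbose = 0
    )
  })

  dall <- xgboost::xgb.DMatrix(x, label = y)
  contrib <- predict(booster, dall, predcontrib = TRUE)
  colnames(contrib) <- c(features, "BIAS")
  shap <- contrib[, features, drop = FALSE]
  baseline <- contrib[1, "BIAS"]

  importance <- tibble::tibble(
    feature = features,
    importance = colMeans(abs(shap)),
    dependence_rho = unname(vapply(features, function(f) {
      if (stats::sd(x[, f]) == 0 || stats::sd(shap[, f]) == 0) return(0)
      stats::cor(x[, f], shap[, f], method = "spearman")
    }, numeric(1)))
  ) |>
    dplyr::mutate(dependence_sign = sign(.data$dependence_rho)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$feature) |>
    dplyr::mutate(rank = dplyr::row_number())

  structure(
    list(
      importance = importance, shap = shap, baseline = baseline,
      prediction = predict(booster, dall),
      model = booster, screen = scr, features = features,
      response = response,
      params = params, nrounds_max = nrounds,
      best_iteration = xgboost::xgb.attr(booster, "best_iteration"),
      early_stopping_rounds = early_stopping_rounds,
      seed = seed, n_obs = nrow(x)
    ),
    class = "iwue_attribution"
  )
}

#' @export
print.iwue_attribution <- function(x, ...) {
  cat(sprintf("<iwue_attribution> %s ~ %d features, n = %d, seed = %d\n",
              x$response, length(x$features), x$n_obs, x$seed))
  print(as.data.frame(utils::head(x$importance, 10)), digits = 3,
        row.names = FALSE)
  invisible(x)
}

#' Tidy a driver-attribution result
#'
#' @param x An `iwue_attribution` object.
#' @param ... Unused.
#' @return The importance tibble: one row per feature with mean |SHAP|
#'   importance, dependence rank correlation and sign, and rank.
#' @method tidy iwue_attribution
#' @export
tidy.iwue_attribution <- function(x, ...) x$importance

#' Ranked importance report with dependence summaries
#'
#' @param result An `iwue_attribution` object.
#' @param top_k Keep the `top_k` most important features (all if larger
#'   than the number of features).
#' @param dir Optional directory; if given, `importance.csv` and
#'   `dependence.csv` are written there.
#' @return A list with `importance` (ranked tibble) and `dependence`
#'   (per-feature tibble of feature value vs SHAP value, long format).
#' @export
rank_report <- function(result, top_k = Inf, dir = NULL) {
  stopifnot(inherits(result, "iwue_attribution"))
  imp <- utils::head(result$importance, min(top_k, nrow(result$importance)))
  dep <- purrr::list_rbind(purrr::map(imp$feature, function(f) {
    tibble::tibble(feature = f,
                   shap = result$shap[, f],
                   row = seq_len(nrow(result$shap)))
  }))
  out <- list(importance = imp, dependence = dep)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(imp, file.path(dir, "importance.csv"))
    readr::write_csv(dep, file.path(dir, "dependence.csv"))
  }
  out
}

#' Plot SHAP importance ranking
#'
#' Horizontal bar chart of mean |SHAP| importance, coloured by the
#' dependence sign.
#'
#' @param object An `iwue_attribution` object.
#' @param top_k Number of features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot iwue_attribution
#' @export
autoplot.iwue_attribution <- function(object, top_k = 10, ...) {
  imp <- utils::head(object$importance, top_k)
  ggplot2::ggplot(
    imp,
    ggplot2::aes(x = .data$importance,
                 y = stats::reorder(.data$feature, .data$importance),
                 fill = factor(.data$dependence_sign))
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |SHAP| (response units)", y = NULL,
                  fill = "dependence sign") +
    ggplot2::theme_minimal()
}

#' SHAP dependence plot for one feature
#'
#' @param object An `iwue_attribution` object.
#' @param feature Feature name.
#' @param data The data the attribution was fitted on (for the feature
#'   values on the x axis).
#' @return A ggplot of SHAP value against feature value.
#' @export
plot_dependence <- function(object, feature, data) {
  stopifnot(inherits(object, "iwue_attribution"),
            feature %in% object$features)
  keep <- stats::complete.cases(data[c(object$features, object$response)])
  df <- tibble::tibble(value = data[[feature]][keep],
                       shap = object$shap[, feature])
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$shap)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = feature, y = "SHAP value") +
    ggplot2::theme_minimal()
}
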