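#' Fit an elevational trend with a species random intercept
#'
#' REML linear mixed-effects model `response ~ fixed + (1 | group)` (random
#' slopes optionally added with `random_slope = TRUE`). Rows with missing
#' values in any model variable are dropped listwise with a message.
#' Fixed-effect p-values use the Satterthwaite degrees-of-freedom
#' approximation (recorded in the fit metadata). A singular fit (zero
#' group variance) is returned with a warning, not an error.
#'
#' @param data A data frame (e.g. the transect table).
#' @param response Response column name (default `"iwue"`).
#' @param fixed Fixed covariate column name(s) (default `"elevation_km"`;
#'   if absent but `elevation_m` is present, `elevation_km` is derived).
#' @param group Grouping factor column (default `"species_id"`).
#' @param random_slope If `TRUE`, the first fixed covariate also gets a
#'   correlated random slope by group.
#' @return An object of class `iwue_lmm` wrapping the `lmerModLmerTest`
#'   fit, with variance components, Nakagawa R-squared values, coefficient
#'   table, and metadata.
#' @examples
#' sim <- simulate_transect(transect_config(n_sites = 30, seed = 2))
#' tbl <- compute_iwue(sim$data)
#' fit <- fit_trend_lmm(dplyr::filter(tbl, pathway == "C3"))
#' glance(fit)
#' @export
fit_trend_lmm <- function(data, response = "iwue", fixed = "elevation_km",
                          group = "species_id", random_slope = FALSE) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (!"elevation_km" %in% names(data) && "elevation_m" %in% names(data)) {
    data$elevation_km <- data$elevation_m / 1000
  }
  vars <- c(response, fixed, group)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("Missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(data[vars])
  if (!all(complete)) {
    message("Dropping ", sum(!complete), " row(s) with missing values ",
            "(listwise deletion).")
    data <- data[complete, ]
  }
  if (nrow(data) < 10) stop("Need at least 10 observations.", call. = FALSE)
  if (length(unique(data[[group]])) < 2) {
    stop("Grouping factor must have at least 2 levels.", call. = FALSE)
  }
  re <- if (random_slope) sprintf("(1 + %s | %s)", fixed[1], group)
        else sprintf("(1 | %s)", group)
  fml <- stats::as.formula(
    paste(response, "~", paste(fixed, collapse = " + "), "+", re)
  )
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  if (lme4::isSingular(fit)) {
    warning("Singular fit: estimated group variance is (near) zero.",
            call. = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_group <- sum(vc$vcov[vc$grp != "Residual" & is.na(vc$var2)])
  sigma2_resid <- vc$vcov[vc$grp == "Residual"]
  fixed_pred <- as.vector(
    stats::model.matrix(fit) %*% lme4::fixef(fit)
  )
  sigma2_fixed <- stats::var(fixed_pred) * (length(fixed_pred) - 1) /
    length(fixed_pred)
  r2 <- r2_components(sigma2_fixed, sigma2_group, sigma2_resid)
  coefs <- summary(fit)$coefficients
  structure(
    list(
      fit = fit, formula = fml,
      response = response, fixed = fixed, group = group,
      coefficients = tibble::tibble(
        term = rownames(coefs),
        estimate = unname(coefs[, "Estimate"]),
        std_error = unname(coefs[, "Std. Error"]),
        df = unname(coefs[, "df"]),
        statistic = unname(coefs[, "t value"]),
        p_value = unname(coefs[, "Pr(>|t|)"]),
        conf_low = .data$estimate -
          stats::qt(0.975, .data$df) * .data$std_error,
        conf_high = .data$estimate +
          stats::qt(0.975, .data$df) * .data$std_error
      ),
      sigma2_fixed = sigma2_fixed,
      sigma2_group = sigma2_group,
      sigma2_resid = sigma2_resid,
      r2_marginal = r2[["r2_marginal"]],
      r2_conditional = r2[["r2_conditional"]],
      n_obs = stats::nobs(fit),
      n_groups = length(unique(data[[group]])),
      p_value_method = "Satterthwaite (lmerTest)",
      estimation = "REML"
    ),
    class = "iwue_lmm"
  )
}

#' Marginal and conditional R-squared from variance components
#'
#' The variance-decomposition R-squared for a mixed model with a normal
#' response and identity link:
#' `R2m = s2_fixed / (s2_fixed + s2_group + s2_resid)` (fixed effects
#' alone) and `R2c = (s2_fixed + s2_group) / (same denominator)` (fixed
#' plus random effects), where `s2_fixed` is the variance of the
#' fixed-effect linear predictor.
#'
#' @param sigma2_fixed,sigma2_group,sigma2_resid Non-negative variance
#'   components.
#' @return A named numeric vector `c(r2_marginal, r2_conditional)`.
#' @examples
#' r2_components(2, 1, 1) # 0.5, 0.75
#' @export
r2_components <- function(sigma2_fixed, sigma2_group, sigma2_resid) {
  comps <- c(sigma2_fixed, sigma2_group, sigma2_resid)
  if (any(comps < 0)) stop("Variance components must be >= 0.", call. = FALSE)
  total <- sum(comps)
  if (total == 0) {
    stop("All variance components are zero; R-squared undefined.",
         call. = FALSE)
  }
  c(r2_marginal = sigma2_fixed / total,
    r2_conditional = (sigma2_fixed + sigma2_group) / total)
}

#' @rdname r2_components
#' @param fit An `iwue_lmm` object.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "iwue_lmm"))
  r2_components(fit$sigma2_fixed, fit$sigma2_group, fit$sigma2_resid)
}

#' Fit elevational iWUE trends separately per photosynthetic pathway
#'
#' Convenience wrapper: one [fit_trend_lmm()] per pathway subset.
#'
#' @inheritParams fit_trend_lmm
#' @return A named list of `iwue_lmm` fits (`C3`, `C4`; pathways with too
#'   few data are skipped with a message).
#' @export
fit_pathway_trends <- function(data, response = "iwue",
                               fixed = "elevation_km",
                               group = "species_id") {
  fits <- list()
  for (p in c("C3", "C4")) {
    sub <- dplyr::filter(data, .data$pathway == p)
    fits[[p]] <- tryCatch(
      fit_trend_lmm(sub, response = response, fixed = fixed, group = group),
      error = function(e) {
        message("Skipping pathway ", p, ": ", conditionMessage(e))
        NULL
      }
    )
  }
  fits[!vapply(fits, is.null, logical(1))]
}

#' @export
print.iwue_lmm <- function(x, ...) {
  cat("<iwue_lmm> ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d observations, %d groups (%s); %s, p-values: %s\n",
              x$n_obs, x$n_groups, x$group, x$estimation, x$p_value_method))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  cat(sprintf("  R2 marginal = %.3f, conditional = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Tidy a mixed-model trend fit
#'
#' @param x An `iwue_lmm` object.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term: estimate, standard
#'   error, Satterthwaite df, t statistic, p-value, and 95% confidence
#'   bounds.
#' @method tidy iwue_lmm
#' @export
tidy.iwue_lmm <- function(x, ...) x$coefficients

#' One-row model summary of a mixed-model trend fit
#'
#' @param x An `iwue_lmm` object.
#' @param ... Unused.
#' @return A one-row tibble with the variance components, marginal and
#'   conditional R-squared, and sample sizes.
#' @method glance iwue_lmm
#' @export
glance.iwue_lmm <- function(x, ...) {
  tibble::tibble(
    sigma2_fixed = x$sigma2_fixed,
    sigma2_group = x$sigma2_group,
    sigma2_resid = x$sigma2_resid,
    r2_marginal = x$r2_marginal,
    r2_conditional = x$r2_conditional,
    n_obs = x$n_obs,
    n_groups = x$n_groups
  )
}

#' Plot an elevational trend fit
#'
#' Observed values coloured by group with the population-level (fixed
#' effects only) fitted line.
#'
#' @param object An `iwue_lmm` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot iwue_lmm
#' @export
autoplot.iwue_lmm <- function(object, ...) {
  fit <- object$fit
  mf <- stats::model.frame(fit)
  xvar <- object$fixed[1]
  df <- tibble::tibble(
    x = mf[[xvar]],
    y = mf[[object$response]],
    group = mf[[object$group]],
    fixed_pred = as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fixed_pred), linewidth = 1) +
    ggplot2::labs(
      x = xvar, y = object$response,
      subtitle = sprintf("R2m = %.2f, R2c = %.2f",
                         object$r2_marginal, object$r2_conditional)
    ) +
    ggplot2::theme_minimal()
}
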