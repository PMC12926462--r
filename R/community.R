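#' Shannon-Wiener diversity index
#'
#' `H = -sum(p_i * log(p_i))` over species with positive abundance, in
#' nats (natural logarithm). Invariant to rescaling of the abundances.
#'
#' @param abundances Non-negative abundances (counts or cover) for the
#'   species of one community.
#' @return Shannon index in nats, bounded by `[0, log(S)]` for `S` species.
#' @examples
#' shannon_index(c(2, 1, 1))
#' @export
shannon_index <- function(abundances) {
  if (any(abundances < 0)) stop("Abundances must be non-negative.", call. = FALSE)
  total <- sum(abundances)
  if (total <= 0) {
    stop("Shannon index undefined for an all-zero community.", call. = FALSE)
  }
  p <- abundances[abundances > 0] / total
  -sum(p * log(p))
}

#' Species richness as the mean count per plot
#'
#' Counts species with positive abundance in each plot and averages the
#' counts; an empty plot contributes zero.
#'
#' @param plot_abundances A data frame with columns `plot_id`, `species_id`
#'   and `abundance` (one row per species per plot), or a list of abundance
#'   vectors (one element per plot).
#' @return Mean number of species per plot (a single number).
#' @examples
#' species_richness(list(c(1, 2, 0, 3), c(1, 1)))
#' @export
species_richness <- function(plot_abundances) {
  if (is.data.frame(plot_abundances)) {
    stopifnot(all(c("plot_id", "abundance") %in% names(plot_abundances)))
    counts <- plot_abundances |>
      dplyr::group_by(.data$plot_id) |>
      dplyr::summarise(n_sp = sum(.data$abundance > 0), .groups = "drop")
    return(mean(counts$n_sp))
  }
  if (!is.list(plot_abundances) || length(plot_abundances) == 0) {
    stop("Provide a data frame or a non-empty list of abundance vectors.",
         call. = FALSE)
  }
  mean(vapply(plot_abundances, function(x) sum(x > 0), numeric(1)))
}

#' Community-weighted mean of a trait
#'
#' `CWM = sum(w_i * trait_i) / sum(w_i)`. Weights are typically the
#' relative abundances of the dominant species (biomass weighting works
#' identically — pass biomass as `weights`). Invariant to rescaling of the
#' weights and bounded by the range of the trait values.
#'
#' @param traits Trait values per species.
#' @param weights Non-negative weights per species, not all zero.
#' @return The weighted mean trait value.
#' @examples
#' community_weighted_mean(c(10, 20), c(1, 3))
#' @export
community_weighted_mean <- function(traits, weights) {
  if (length(traits) != length(weights)) {
    stop("`traits` and `weights` must have equal length.", call. = FALSE)
  }
  if (any(weights < 0)) stop("Weights must be non-negative.", call. = FALSE)
  if (sum(weights) <= 0) {
    stop("CWM undefined when all weights are zero.", call. = FALSE)
  }
  sum(weights * traits) / sum(weights)
}

#' Per-site diversity metrics from an abundance sheet
#'
#' Aggregates a long plot-level abundance table into one row per site with
#' species richness (mean species count per plot) and the Shannon-Wiener
#' index of the site-pooled abundances.
#'
#' @param abundance A data frame with columns `site_id`, `plot_id`,
#'   `species_id`, `abundance`.
#' @return A tibble with columns `site_id`, `sr`, `shannon`.
#' @export
site_community_metrics <- function(abundance) {
  stopifnot(all(c("site_id", "plot_id", "species_id", "abundance") %in%
                  names(abundance)))
  abundance |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      sr = species_richness(dplyr::pick(dplyr::everything())),
      shannon = shannon_index(tapply(.data$abundance, .data$species_id, sum)),
      .groups = "drop"
    )
}
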