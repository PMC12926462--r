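# Small configurations used across test files. tiny_config keeps the
# generator cheap; noiseless_config switches every stochastic term off so
# the forward/inverse chain is exact.

tiny_config <- function(seed = 1L, ...) {
  transect_config(n_sites = 25, seed = seed, ...)
}

noiseless_config <- function(seed = 1L, ...) {
  transect_config(
    n_sites = 25, species_sd = 0, residual_sd = 0,
    climate_noise_frac = 0, d18o_sd = 0, seed = seed, ...
  )
}

# Orthonormal, mean-zero basis for constructing exact sample correlations.
orthonormal_basis <- function(n, k, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n * k), n, k)
    m <- scale(m, center = TRUE, scale = FALSE)
    qr.Q(qr(m))
  })
}

# Independent single-driver dataset: y responds to feature `a` only.
single_driver_data <- function(n = 250, noise_sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    x <- as.data.frame(matrix(stats::rnorm(n * 5), n, 5))
    names(x) <- c("a", "b", "c", "d", "e")
    x$y <- 2 * x$a + stats::rnorm(n, 0, noise_sd)
    x
  })
}
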