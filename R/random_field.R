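# Spatially autocorrelated noise for the synthetic scenario generator.

#' Gaussian random field on a regular grid
#'
#' Draws standard white noise and smooths it with a separable Gaussian kernel,
#' yielding an approximately unit-variance field whose autocorrelation is
#' Gaussian in distance: corr(d) ~ exp(-d^2 / range_cells^2), i.e. it drops to
#' 1/e at a lag of `range_cells` cells. The white noise is padded so edge cells
#' receive the same smoothing as interior cells. Draws consume the current R
#' RNG state, so results are reproducible under `set.seed()`.
#'
#' @param nlat,nlon Field dimensions.
#' @param range_cells Correlation length in cell units (lag at which the
#'   autocorrelation falls to 1/e). Default 3.
#' @return A `nlat x nlon` numeric matrix with mean ~0 and variance ~1.
#' @export
gaussian_random_field <- function(nlat, nlon, range_cells = 3) {
  if (range_cells <= 0) stop("`range_cells` must be positive")
  sigma <- range_cells / 2
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  z <- matrix(stats::rnorm((nlat + 2 * half) * (nlon + 2 * half)),
              nrow = nlat + 2 * half)
  f <- stats::filter(z, k, sides = 2)              # along rows of each column
  f <- t(stats::filter(t(f), k, sides = 2))        # along columns of each row
  f <- matrix(as.numeric(f), nrow = nlat + 2 * half)
  out <- f[(half + 1):(half + nlat), (half + 1):(half + nlon), drop = FALSE]
  # Separable convolution of unit white noise has variance (sum k^2)^2.
  out / sum(k^2)
}
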