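# Scenario differencing, regional aggregation of carbon stocks/flows, and
# the serial-correlation-corrected significance test.

#' Difference carbon fields between two scenarios
#'
#' Forms PFT-weighted per-cell totals for each indicator and differences
#' them, Halving-N minus Baseline. Both fields must share the grid and PFT
#' set.
#'
#' @param fields_halving,fields_baseline `carbon_fields` objects.
#' @return Object of class `delta_maps`: list of matrices `npp`
#'   (tC/ha/yr), `soil` and `biomass` (tC/ha), plus the grid.
#' @export
scenario_difference <- function(fields_halving, fields_baseline) {
  if (!identical(dim(fields_halving$soil), dim(fields_baseline$soil)) ||
      !identical(dimnames(fields_halving$soil)[[3]],
                 dimnames(fields_baseline$soil)[[3]]))
    stop("carbon fields do not share the same grid and PFT set")
  structure(
    list(npp = cell_total(fields_halving, "npp") -
           cell_total(fields_baseline, "npp"),
         soil = cell_total(fields_halving, "soil") -
           cell_total(fields_baseline, "soil"),
         biomass = cell_total(fields_halving, "biomass") -
           cell_total(fields_baseline, "biomass"),
         grid = fields_halving$grid),
    class = "delta_maps"
  )
}

#' Partition the grid into synthetic regions
#'
#' Splits the domain into `n_regions` longitude bands with near-equal cell
#' counts — a stand-in for country masks that is guaranteed to partition the
#' grid (every cell in exactly one region).
#'
#' @param grid A `halven_grid`.
#' @param n_regions Number of regions.
#' @return Integer matrix (lat x lon) with levels attribute `regions`
#'   (`region_01`, ...).
#' @export
generate_region_mask <- function(grid, n_regions = 6) {
  if (n_regions < 1 || n_regions > grid$nlon)
    stop("`n_regions` must be between 1 and the number of longitude columns")
  band <- as.integer(cut(seq_len(grid$nlon), breaks = n_regions,
                         labels = FALSE))
  mask <- matrix(rep(band, each = grid$nlat), nrow = grid$nlat)
  attr(mask, "regions") <- sprintf("region_%02d", seq_len(n_regions))
  mask
}

#' Aggregate a density map into regional totals
#'
#' Converts per-cell densities (tC/ha or tC/ha/yr) to totals in MtC (or
#' MtC/yr): `total = sum over cells of density * cell_area_ha * 1e-6`. A row
#' per region plus a whole-domain `EU` row is returned; when the mask
#' partitions the grid the regional totals sum exactly to the EU total.
#'
#' @param density Matrix of per-cell densities on `grid`.
#' @param grid A `halven_grid`.
#' @param region_mask Optional integer matrix from [generate_region_mask()];
#'   `NULL` gives the EU row only.
#' @return Data frame with columns `region` and `total`.
#' @export
aggregate_totals <- function(density, grid, region_mask = NULL) {
  if (!identical(dim(density), dim(grid$cell_area_ha)))
    stop("`density` is not on the supplied grid")
  contrib <- density * grid$cell_area_ha * 1e-6
  out <- data.frame(region = "EU", total = sum(contrib),
                    stringsAsFactors = FALSE)
  if (!is.null(region_mask)) {
    if (!identical(dim(region_mask), dim(density)))
      stop("`region_mask` is not on the supplied grid")
    regions <- attr(region_mask, "regions")
    if (is.null(regions)) regions <- sprintf("region_%02d",
                                             sort(unique(as.vector(region_mask))))
    tot <- vapply(seq_along(regions),
                  function(r) sum(contrib[region_mask == r]), numeric(1))
    out <- rbind(out, data.frame(region = regions, total = tot,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Lag-1 autocorrelation of a series (moment estimator)
#' @noRd
lag1_autocorrelation <- function(x) {
  x <- x - mean(x)
  v <- sum(x^2)
  if (v <= 0) return(0)
  sum(x[-1] * x[-length(x)]) / v
}

#' Significance mask from annual difference series, corrected for serial
#' correlation
#'
#' One-sample Student t-test of the mean annual difference against zero in
#' every cell, with the standard error corrected for temporal serial
#' correlation through the effective sample size
#' \eqn{n_{eff} = n (1 - r_1)/(1 + r_1)}, where \eqn{r_1} is the cell's
#' lag-1 autocorrelation. The moment estimate of \eqn{r_1} is biased low in
#' short series, which would leave the corrected test anti-conservative, so
#' the first-order Marriott-Pope/Kendall bias correction
#' \eqn{\hat r_1 + (1 + 3\hat r_1)/n} is applied before clipping to
#' \[0, 0.99\] (negative estimates are not used to inflate the sample). The
#' t statistic uses \eqn{SE = s/\sqrt{n_{eff}}} with \eqn{n_{eff} - 1}
#' degrees of freedom. Cells with zero variance are significant iff their
#' constant difference is nonzero.
#'
#' @param series 3-d array (lat x lon x years) of annual differences, at
#'   least 3 years.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `significance_mask`: list with logical matrix
#'   `significant`, matrices `p_value` and `r1`, and parameters `n_years`
#'   and `alpha`.
#' @export
significance_mask <- function(series, alpha = 0.05) {
  if (length(dim(series)) != 3) stop("`series` must be a 3-d array")
  n <- dim(series)[3]
  if (n < 3) stop("at least 3 annual differences are required per cell")
  nlat <- dim(series)[1]; nlon <- dim(series)[2]
  p <- matrix(NA_real_, nlat, nlon)
  r1m <- matrix(NA_real_, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    x <- series[i, j, ]
    m <- mean(x); s <- stats::sd(x)
    r1 <- lag1_autocorrelation(x)
    r1 <- min(max(r1 + (1 + 3 * r1) / n, 0), 0.99)
    r1m[i, j] <- r1
    if (s == 0) {
      p[i, j] <- if (m == 0) 1 else 0
    } else {
      # floor n_eff at 2 so the t reference distribution stays defined even
      # for short, strongly autocorrelated series
      n_eff <- max(n * (1 - r1) / (1 + r1), 2)
      tstat <- m / (s / sqrt(n_eff))
      p[i, j] <- 2 * stats::pt(-abs(tstat), df = n_eff - 1)
    }
  }
  structure(list(significant = p < alpha, p_value = p, r1 = r1m,
                 n_years = n, alpha = alpha),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf(
    "<significance_mask> %d years, alpha %.3g: %.1f%% of cells significant\n",
    x$n_years, x$alpha, 100 * mean(x$significant)))
  invisible(x)
}
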