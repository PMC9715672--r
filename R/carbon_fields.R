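# Synthetic per-PFT carbon densities (equilibrium fields emulating a
# land-surface model's output) and single-pool soil-carbon relaxation.

#' Default equilibrium carbon densities per plant functional type
#'
#' Mean NPP (tC/ha/yr), soil carbon (tC/ha) and biomass carbon (tC/ha) for
#' each PFT. The defaults respect the orderings the scenario logic relies
#' on: natural grass and forest soils hold more carbon per hectare than
#' cropland soils (converting cropland to fallow/grass gains soil carbon,
#' converting pasture to cropland loses it), and permanent herbaceous and
#' forest vegetation fixes more carbon per hectare and year than annual
#' crops with their bare-soil periods, so losing grazing land also lowers
#' NPP.
#'
#' @param soil,npp,biomass Optional named numeric vectors overriding the
#'   default mean for any PFT.
#' @return Data frame with columns `pft`, `npp`, `soil`, `biomass`.
#' @export
carbon_means <- function(soil = NULL, npp = NULL, biomass = NULL) {
  means <- data.frame(
    pft = PFT_CLASSES,
    npp = c(4.0, 4.0, 4.5, 5.0, 4.8, 5.2, 5.2, 5.2, 5.2, 0.1),
    soil = c(50, 50, 50, 85, 80, 95, 95, 95, 95, 8),
    biomass = c(5, 5, 5, 8, 8, 90, 90, 90, 90, 0.5),
    stringsAsFactors = FALSE
  )
  for (nm in names(soil)) means$soil[means$pft == nm] <- soil[[nm]]
  for (nm in names(npp)) means$npp[means$pft == nm] <- npp[[nm]]
  for (nm in names(biomass)) means$biomass[means$pft == nm] <- biomass[[nm]]
  if (any(means$npp < 0) || any(means$soil < 0) || any(means$biomass < 0))
    stop("carbon density means must be non-negative")
  means
}

#' Generate spatially autocorrelated per-PFT carbon density fields
#'
#' For each PFT and indicator, density = configured mean + sd * Gaussian
#' random field (correlation length `range_cells`), floored at a small
#' positive value. The noise depends only on the grid and the config seed,
#' not on the land-use map, so the Baseline and Halving-N scenarios see
#' identical per-PFT densities and their difference reflects land-use change
#' alone.
#'
#' @param grid A `halven_grid`.
#' @param pft A `pft_layer` giving per-cell PFT fractions (the weights used
#'   when forming cell totals).
#' @param config A [scenario_config()]; supplies the seed.
#' @param means Per-PFT means, see [carbon_means()].
#' @param noise_sd Named vector: noise sd for `npp` (tC/ha/yr), `soil` and
#'   `biomass` (tC/ha). Zero gives densities exactly equal to the means.
#' @param range_cells Correlation length of the noise, cells.
#' @return An object of class `carbon_fields`: list with 3-d arrays `npp`,
#'   `soil`, `biomass` (lat x lon x PFT), the PFT `fractions`, and the grid.
#' @export
generate_carbon_fields <- function(grid, pft, config,
                                   means = carbon_means(),
                                   noise_sd = c(npp = 0.4, soil = 6,
                                                biomass = 2),
                                   range_cells = 3) {
  if (!inherits(pft, "pft_layer")) stop("`pft` must be a pft_layer")
  if (any(noise_sd < 0)) stop("`noise_sd` must be non-negative")
  set.seed(config$seed + 101L)
  nlat <- grid$nlat; nlon <- grid$nlon
  pfts <- dimnames(pft$fractions)[[3]]
  miss <- setdiff(pfts, means$pft)
  if (length(miss)) stop("no carbon means for PFT: ",
                         paste(miss, collapse = ", "))
  mk <- function(indicator) {
    arr <- array(0, dim = c(nlat, nlon, length(pfts)),
                 dimnames = list(NULL, NULL, pfts))
    sd_i <- noise_sd[[indicator]]
    for (k in seq_along(pfts)) {
      mu <- means[[indicator]][means$pft == pfts[k]]
      noise <- if (sd_i > 0)
        sd_i * gaussian_random_field(nlat, nlon, range_cells)
      else matrix(0, nlat, nlon)
      arr[, , k] <- pmax(mu + noise, 1e-6)
    }
    arr
  }
  structure(
    list(npp = mk("npp"), soil = mk("soil"), biomass = mk("biomass"),
         fractions = pft$fractions, grid = grid, scenario = pft$scenario),
    class = "carbon_fields"
  )
}

#' @export
print.carbon_fields <- function(x, ...) {
  cat(sprintf("<carbon_fields> %d x %d cells, %d PFTs%s\n",
              dim(x$soil)[1], dim(x$soil)[2], dim(x$soil)[3],
              if (!is.null(x$scenario)) paste0(" [", x$scenario, "]") else ""))
  invisible(x)
}

#' PFT-weighted per-cell total density of one indicator
#'
#' @param fields A `carbon_fields`.
#' @param indicator `"npp"`, `"soil"` or `"biomass"`.
#' @param pfts Optional subset of PFT names (e.g. only grassland PFTs).
#' @return Matrix of densities (tC/ha or tC/ha/yr), the weighted sum across
#'   the selected PFTs.
#' @export
cell_total <- function(fields, indicator = c("soil", "npp", "biomass"),
                       pfts = NULL) {
  indicator <- match.arg(indicator)
  dens <- fields[[indicator]]
  all_pfts <- dimnames(dens)[[3]]
  if (is.null(pfts)) pfts <- all_pfts
  miss <- setdiff(pfts, all_pfts)
  if (length(miss)) stop("unknown PFT: ", paste(miss, collapse = ", "))
  out <- matrix(0, dim(dens)[1], dim(dens)[2])
  for (p in pfts) out <- out + fields$fractions[, , p] * dens[, , p]
  out
}

#' Single-pool soil-carbon relaxation toward a new equilibrium
#'
#' After an instantaneous land-use change, soil carbon approaches its new
#' equilibrium exponentially:
#' \deqn{c(t) = c_{eq} + (c_0 - c_{eq}) e^{-t/\tau}}
#' One pool, one time constant; with the default \eqn{\tau = 40} yr the
#' stock has covered ~98% of the transition after 150 years.
#'
#' @param c_initial Initial stock(s) (tC/ha or MtC).
#' @param c_equilibrium New equilibrium stock(s), same shape/units.
#' @param tau Relaxation time, years (> 0).
#' @param t_years Elapsed time(s), years (>= 0).
#' @return Stock at `t_years`, monotone between `c_initial` and
#'   `c_equilibrium`.
#' @examples
#' soil_carbon_relaxation(100, 200, tau = 40, t_years = 40)  # 200 - 100/e
#' @export
soil_carbon_relaxation <- function(c_initial, c_equilibrium, tau, t_years) {
  if (any(tau <= 0)) stop("`tau` must be positive")
  if (any(t_years < 0)) stop("`t_years` must be non-negative")
  c_equilibrium + (c_initial - c_equilibrium) * exp(-t_years / tau)
}
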