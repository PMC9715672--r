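# Build per-land-use indicator states (levels and areas in both scenarios)
# from gridded layers, and run the LMDI decomposition on them.

CARBON_GROUPS <- list(cropland = CROP_PFTS, grassland = GRASS_PFTS,
                      forest = FOREST_PFTS, other = "bare_soil")

predicts_groups <- function() {
  list(cropland = PREDICTS_CROP_CLASSES,
       grassland = c("pasture_light", "pasture_intense", "rangeland"),
       forest = c("primary", "secondary"),
       other = "urban")
}

# Group level (MtC or MtC/yr) and area (Mha) of one carbon-fields object.
carbon_group_level <- function(fields, indicator, pfts) {
  area <- fields$grid$cell_area_ha
  E <- sum(cell_total(fields, indicator, pfts) * area) * 1e-6
  A <- 0
  for (p in pfts) A <- A + sum(fields$fractions[, , p] * area)
  c(E = E, A = A * 1e-6)
}

#' Per-land-use indicator states for a carbon indicator
#'
#' Levels are the PFT-group totals (MtC, or MtC/yr for NPP) in each
#' scenario; areas are the group areas in Mha. For soil carbon an optional
#' relaxation horizon scales the Halving-N level toward its new equilibrium:
#' `E_hN(t) = E_b + (E_hN_eq - E_b)(1 - exp(-t/tau))`, applied per group so
#' the group levels stay consistent with the relaxed total map.
#'
#' @param fields_baseline,fields_halving `carbon_fields` for the two
#'   scenarios (same grid and PFT set).
#' @param indicator `"soil"`, `"npp"` or `"biomass"`.
#' @param horizon,tau Optional relaxation horizon and time constant (years);
#'   both or neither.
#' @return Data frame with columns `land_use` (cropland, grassland, forest,
#'   other), `E_b`, `E_hN`, `A_b`, `A_hN`.
#' @export
carbon_breakdown_states <- function(fields_baseline, fields_halving,
                                    indicator = c("soil", "npp", "biomass"),
                                    horizon = NULL, tau = NULL) {
  indicator <- match.arg(indicator)
  if (xor(is.null(horizon), is.null(tau)))
    stop("supply both `horizon` and `tau`, or neither")
  rows <- lapply(names(CARBON_GROUPS), function(g) {
    b <- carbon_group_level(fields_baseline, indicator, CARBON_GROUPS[[g]])
    h <- carbon_group_level(fields_halving, indicator, CARBON_GROUPS[[g]])
    E_h <- h[["E"]]
    if (!is.null(horizon))
      E_h <- soil_carbon_relaxation(b[["E"]], h[["E"]], tau, horizon)
    data.frame(land_use = g, E_b = b[["E"]], E_hN = E_h,
               A_b = b[["A"]], A_hN = h[["A"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-land-use indicator states for species richness
#'
#' The EU-scale SR level is the area-weighted mean of cell SR%, which is
#' linear in the class fractions; each land-use group's level is therefore
#' the group's additive contribution (in percentage points of the primary-
#' vegetation reference) to that mean, and group levels sum exactly to the
#' EU mean SR%. Because of this linearity the per-land-use differences also
#' sum exactly to the overall SR change, matching a direct projection in
#' which only one land use is allowed to change at a time.
#'
#' @param layer_baseline,layer_halving `predicts_layer`s on one grid.
#' @param coefs A [biodiversity_coefficients()] object.
#' @return Data frame with columns `land_use`, `E_b`, `E_hN`, `A_b`, `A_hN`
#'   (levels in SR percentage points, areas in Mha).
#' @export
sr_breakdown_states <- function(layer_baseline, layer_halving, coefs) {
  grid <- layer_baseline$grid
  stopifnot_same_grid(layer_baseline$fractions, layer_halving$fractions)
  w <- grid$cell_area_ha / sum(grid$cell_area_ha)
  keys <- dimnames(layer_baseline$fractions)[[3]]
  sr0 <- coef_lookup(coefs, "primary", "sr_coef")
  rel <- exp(coef_lookup(coefs, keys, "sr_coef") - sr0)
  names(rel) <- keys
  groups <- predicts_groups()
  level <- function(layer, classes) {
    out <- 0
    for (cl in intersect(classes, keys))
      out <- out + sum(w * layer$fractions[, , cl]) * rel[[cl]]
    100 * out
  }
  area <- function(layer, classes) {
    out <- 0
    for (cl in intersect(classes, keys))
      out <- out + sum(layer$fractions[, , cl] * grid$cell_area_ha)
    out * 1e-6
  }
  rows <- lapply(names(groups), function(g) {
    data.frame(land_use = g,
               E_b = level(layer_baseline, groups[[g]]),
               E_hN = level(layer_halving, groups[[g]]),
               A_b = area(layer_baseline, groups[[g]]),
               A_hN = area(layer_halving, groups[[g]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' LMDI breakdown across land uses
#'
#' Runs [lmdi_breakdown()] on a per-land-use state table, requiring at least
#' the cropland, grassland and forest rows.
#'
#' @param states Data frame as from [carbon_breakdown_states()] or
#'   [sr_breakdown_states()].
#' @param indicator Indicator label recorded in the result; `"bii"` errors.
#' @param floor Positive floor for levels/areas before logs.
#' @return A `breakdown_result` data frame, one row per land use.
#' @export
breakdown_by_landuse <- function(states, indicator = NULL, floor = 1e-9) {
  miss <- setdiff(c("cropland", "grassland", "forest"), states$land_use)
  if (length(miss))
    stop("missing land-use rows: ", paste(miss, collapse = ", "))
  lmdi_breakdown(states, indicator = indicator, floor = floor)
}
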