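# Synthetic scenario generator: gridded Baseline / Halving-N land-use pairs
# for the two economic archetypes that bracket the policy response — massive
# land abandonment (supply-side model behaviour) and crop extensification
# (partial-equilibrium model behaviour).

#' Configuration for a synthetic scenario pair
#'
#' Bundles the policy and generator parameters. The policy lever is the
#' fraction of baseline nitrogen application retained (`n_policy_fraction`,
#' default 0.5, i.e. halving the 150 kgN/ha baseline). The archetype decides
#' how the economic model reallocates land: `"abandonment"` moves cropland
#' into fallow and pasture; `"extensification"` converts pasture to cropland
#' at lower per-hectare yields.
#'
#' @param archetype `"abandonment"` or `"extensification"`.
#' @param n_baseline Baseline N application, kgN/ha (default 150).
#' @param n_policy_fraction Fraction of baseline N kept under the policy, in
#'   (0, 1]; 1 means no policy.
#' @param y_min,y_max,k_half Yield-response parameters, see
#'   [nitrogen_yield_response()].
#' @param soil_tau Soil-carbon relaxation time, years (default 40).
#' @param abandon_frac Fraction of each cropland category abandoned under a
#'   full halving (abandonment archetype; default 0.15).
#' @param convert_frac Fraction of pasture converted to cropland under a full
#'   halving (extensification archetype; default 0.10).
#' @param stock_baseline Baseline ruminant stocking proxy, heads/ha.
#' @param stock_drop Stocking decrease under a full halving, heads/ha.
#' @param noise_spread Log-scale spread of the spatial land-use pattern.
#' @param yield_noise_sd Log-scale sd of the spatial yield pattern.
#' @param range_cells Correlation length of all spatial noise, in cells.
#' @param seed Integer RNG seed; every draw in the generator derives from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(archetype = c("abandonment", "extensification"),
                            n_baseline = 150, n_policy_fraction = 0.5,
                            y_min = 2, y_max = 8, k_half = 100,
                            soil_tau = 40,
                            abandon_frac = 0.15, convert_frac = 0.10,
                            stock_baseline = 1.0, stock_drop = 0.1,
                            noise_spread = 0.6, yield_noise_sd = 0.15,
                            range_cells = 3, seed = 1L) {
  archetype <- match.arg(archetype)
  if (n_policy_fraction <= 0 || n_policy_fraction > 1)
    stop("`n_policy_fraction` must be in (0, 1]")
  if (y_min >= y_max) stop("`y_min` must be smaller than `y_max`")
  if (k_half <= 0) stop("`k_half` must be positive")
  if (soil_tau <= 0) stop("`soil_tau` must be positive")
  if (abandon_frac < 0 || abandon_frac > 1 ||
      convert_frac < 0 || convert_frac > 1)
    stop("`abandon_frac` and `convert_frac` must be in [0, 1]")
  structure(
    list(archetype = archetype, n_baseline = n_baseline,
         n_policy_fraction = n_policy_fraction,
         y_min = y_min, y_max = y_max, k_half = k_half,
         soil_tau = soil_tau, abandon_frac = abandon_frac,
         convert_frac = convert_frac, stock_baseline = stock_baseline,
         stock_drop = stock_drop, noise_spread = noise_spread,
         yield_noise_sd = yield_noise_sd, range_cells = range_cells,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# Economic model emulated by each archetype.
archetype_model <- function(archetype) {
  switch(archetype, abandonment = "AROPAj", extensification = "NLU",
         stop("unknown archetype: ", archetype))
}

# Mean category weights of the baseline landscape, per archetype. Chosen to
# give an EU-like composition: forest-dominated natural land, ~1/3 cropland
# incl. a few percent fallow, and a substantial pasture share.
default_category_weights <- function(archetype) {
  if (archetype == "abandonment") {
    c("Pasture" = 0.16, "Rangeland" = 0.04, "Urban" = 0.03,
      "Other ecosystem" = 0.05, "Forest" = 0.25,
      "Durum wheat" = 0.02, "Tender wheat" = 0.08, "Winter barley" = 0.03,
      "Spring barley" = 0.02, "Oats" = 0.02, "Other cereals" = 0.02,
      "Rice" = 0.005, "Maize" = 0.06, "Fallow" = 0.03, "Beetroot" = 0.01,
      "Rapeseed" = 0.03, "Sunflower" = 0.02, "Soybean" = 0.005,
      "Other legumes" = 0.01, "Potato" = 0.01, "Perennial" = 0.03)
  } else {
    c("Pasture" = 0.20, "Forest" = 0.30, "Urban" = 0.03, "Other" = 0.05,
      "Wheat" = 0.12, "Maize" = 0.07, "Rapeseed" = 0.04, "Sunflower" = 0.03,
      "Sugarbeet" = 0.02, "Fieldpea" = 0.02, "Soybean" = 0.01,
      "Rice" = 0.005, "Millet" = 0.005, "Groundnut" = 0.002,
      "Cassava" = 0.002)
  }
}

#' Construct a land-use fraction map
#'
#' @param fractions 3-d array (lat x lon x category) with category dimnames;
#'   per-cell sums must be 1 within 1e-9 and all entries in \[0, 1\].
#' @param grid A `halven_grid`.
#' @param scenario Scenario label, e.g. `"baseline"` or `"halving_n"`.
#' @param model Economic model name the categories belong to.
#' @return An object of class `landuse_map`.
#' @export
landuse_map <- function(fractions, grid, scenario, model) {
  if (length(dim(fractions)) != 3)
    stop("`fractions` must be a 3-d array (lat x lon x category)")
  if (dim(fractions)[3] > 0 && is.null(dimnames(fractions)[[3]]))
    stop("`fractions` must carry category names in dimnames[[3]]")
  if (dim(fractions)[1] != grid$nlat || dim(fractions)[2] != grid$nlon)
    stop("`fractions` does not match the grid dimensions")
  if (any(fractions < -1e-12) || any(fractions > 1 + 1e-12))
    stop("fractions must lie in [0, 1]")
  if (dim(fractions)[3] > 0) {
    sums <- apply(fractions, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-9))
      stop("per-cell fractions must sum to 1 within 1e-9")
  }
  structure(list(fractions = fractions, grid = grid, scenario = scenario,
                 model = model),
            class = "landuse_map")
}

#' @export
print.landuse_map <- function(x, ...) {
  cat(sprintf("<landuse_map> %s/%s: %d x %d cells, %d categories\n",
              x$model, x$scenario, dim(x$fractions)[1], dim(x$fractions)[2],
              dim(x$fractions)[3]))
  invisible(x)
}

#' Total area of each land-use category
#'
#' @param map A `landuse_map` (or `predicts_layer` / `pft_layer`).
#' @return Named vector of areas in Mha.
#' @export
category_areas_mha <- function(map) {
  fr <- map$fractions
  area <- map$grid$cell_area_ha
  stats::setNames(
    vapply(seq_len(dim(fr)[3]),
           function(k) sum(fr[, , k] * area) / 1e6, numeric(1)),
    dimnames(fr)[[3]])
}

#' Generate a Baseline / Halving-N land-use scenario pair
#'
#' Draws a spatially autocorrelated baseline landscape (softmax of per-
#' category Gaussian random fields around archetype-specific mean weights)
#' and applies the archetype's policy response, scaled by the severity of
#' the nitrogen cut `(1 - n_policy_fraction) / 0.5` so that
#' `n_policy_fraction = 1` reproduces the baseline exactly:
#'
#' * abandonment: a fraction of every cultivated cropland category moves to
#'   fallow (2/3) and pasture (1/3) — cropland area falls, fallow and
#'   grassland rise;
#' * extensification: a fraction of pasture converts to cropland in
#'   proportion to the local crop mix — cropland area rises, pasture falls,
#'   while the policy yield map drops with the reduced N rate.
#'
#' Yield and stocking maps are returned for both scenarios (shared spatial
#' pattern, policy-dependent level) for use by the intensity share models.
#'
#' @param grid A `halven_grid`.
#' @param config A [scenario_config()].
#' @return An object of class `scenario_pair`: list with `baseline` and
#'   `halving` (`landuse_map`s), `yield` and `stocking` (lists of baseline /
#'   halving matrices), plus the `config` and `grid`.
#' @export
generate_scenario_pair <- function(grid, config) {
  if (!inherits(grid, "halven_grid")) stop("`grid` must be a halven_grid")
  if (!inherits(config, "scenario_config"))
    stop("`config` must be a scenario_config")
  set.seed(config$seed)
  nlat <- grid$nlat; nlon <- grid$nlon
  w <- default_category_weights(config$archetype)
  w <- w / sum(w)
  cats <- names(w)
  model <- archetype_model(config$archetype)

  logit <- array(0, dim = c(nlat, nlon, length(cats)),
                 dimnames = list(NULL, NULL, cats))
  for (k in seq_along(cats)) {
    logit[, , k] <- log(w[k]) +
      config$noise_spread * gaussian_random_field(nlat, nlon,
                                                  config$range_cells)
  }
  ex <- exp(logit)
  denom <- apply(ex, c(1, 2), sum)
  base_fr <- sweep(ex, c(1, 2), denom, "/")

  # Shared spatial yield pattern; the level responds to the N rate.
  yield_field <- exp(config$yield_noise_sd *
                       gaussian_random_field(nlat, nlon, config$range_cells))
  y_base <- nitrogen_yield_response(config$n_baseline, config$y_min,
                                    config$y_max, config$k_half) * yield_field
  y_hn <- nitrogen_yield_response(config$n_baseline * config$n_policy_fraction,
                                  config$y_min, config$y_max,
                                  config$k_half) * yield_field

  severity <- (1 - config$n_policy_fraction) / 0.5
  cw <- build_crosswalk(model = model)
  crops <- intersect(crop_categories(cw), cats)  # cultivated; excludes Fallow

  hn_fr <- base_fr
  if (config$archetype == "abandonment") {
    shift <- config$abandon_frac * severity
    moved_total <- matrix(0, nlat, nlon)
    for (cc in crops) {
      moved <- base_fr[, , cc] * shift
      hn_fr[, , cc] <- hn_fr[, , cc] - moved
      moved_total <- moved_total + moved
    }
    hn_fr[, , "Fallow"] <- hn_fr[, , "Fallow"] + moved_total * 2 / 3
    hn_fr[, , "Pasture"] <- hn_fr[, , "Pasture"] + moved_total / 3
  } else {
    conv <- config$convert_frac * severity
    moved <- base_fr[, , "Pasture"] * conv
    hn_fr[, , "Pasture"] <- hn_fr[, , "Pasture"] - moved
    crop_sum <- apply(base_fr[, , crops, drop = FALSE], c(1, 2), sum)
    fallback <- crop_sum <= 0
    for (cc in crops) {
      prop <- ifelse(fallback,
                     as.numeric(cc == "Wheat"),
                     base_fr[, , cc] / pmax(crop_sum, .Machine$double.eps))
      hn_fr[, , cc] <- hn_fr[, , cc] + moved * prop
    }
  }

  stock_base <- matrix(config$stock_baseline, nlat, nlon)
  stock_hn <- pmax(stock_base - config$stock_drop * severity, 0)

  structure(
    list(
      baseline = landuse_map(base_fr, grid, "baseline", model),
      halving = landuse_map(hn_fr, grid, "halving_n", model),
      yield = list(baseline = y_base, halving = y_hn),
      stocking = list(baseline = stock_base, halving = stock_hn),
      config = config, grid = grid
    ),
    class = "scenario_pair"
  )
}

#' @export
print.scenario_pair <- function(x, ...) {
  cat(sprintf("<scenario_pair> %s (%s), seed %d\n",
              x$config$archetype, x$baseline$model, x$config$seed))
  a_b <- category_areas_mha(x$baseline)
  a_h <- category_areas_mha(x$halving)
  cw <- build_crosswalk(model = x$baseline$model)
  crops <- crop_categories(cw, include_fallow = TRUE)
  cat(sprintf("  cropland (incl. fallow): %.1f -> %.1f Mha\n",
              sum(a_b[intersect(crops, names(a_b))]),
              sum(a_h[intersect(crops, names(a_h))])))
  invisible(x)
}
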