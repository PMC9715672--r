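# Pipeline orchestration: generate -> crosswalk -> project -> difference ->
# breakdown -> quadrants, with strict one-way data flow between stages.

#' Pipeline configuration
#'
#' Bundles everything a full run needs. Referenced files are checked at
#' construction time and an error names any missing path. Every source of
#' randomness in the run derives from `seed`.
#'
#' @param grid A `halven_grid` (default: the EU-like 0.5-degree domain).
#' @param archetypes Scenario families to run.
#' @param seed Integer master seed.
#' @param n_policy_fraction Fraction of baseline N kept under the policy.
#' @param coefficients_path Biodiversity coefficient CSV (`NULL`: packaged
#'   synthetic defaults).
#' @param crosswalk_path Crosswalk CSV (`NULL`: packaged default).
#' @param n_regions Number of synthetic regions in the country mask.
#' @param sim_years Relaxation horizon for soil carbon, years.
#' @param n_years Length of the annual difference series for the
#'   significance test (the final-`n_years` window of the simulation).
#' @param alpha Significance level.
#' @param npp_interannual_sd,npp_ar1 Interannual variability (tC/ha/yr) and
#'   lag-1 autocorrelation of the synthetic annual NPP difference series.
#' @param out_dir Optional output directory for [write_run()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = generate_grid(),
                            archetypes = c("abandonment", "extensification"),
                            seed = 1L,
                            n_policy_fraction = 0.5,
                            coefficients_path = NULL,
                            crosswalk_path = NULL,
                            n_regions = 6,
                            sim_years = 150,
                            n_years = 50,
                            alpha = 0.05,
                            npp_interannual_sd = 0.15,
                            npp_ar1 = 0.5,
                            out_dir = NULL) {
  archetypes <- match.arg(archetypes, several.ok = TRUE)
  for (p in c(coefficients_path, crosswalk_path)) {
    if (!is.null(p) && !file.exists(p))
      stop("configured file does not exist: ", p)
  }
  if (sim_years <= 0 || n_years < 3) stop("invalid simulation horizon")
  structure(
    list(grid = grid, archetypes = archetypes, seed = as.integer(seed),
         n_policy_fraction = n_policy_fraction,
         coefficients_path = coefficients_path,
         crosswalk_path = crosswalk_path,
         n_regions = n_regions, sim_years = sim_years, n_years = n_years,
         alpha = alpha, npp_interannual_sd = npp_interannual_sd,
         npp_ar1 = npp_ar1, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized top-level fields: `grid` (lat_min, lat_max, lon_min, lon_max,
#' resolution), plus any scalar argument of [pipeline_config()]. Unknown
#' fields are an error so that typos cannot silently fall back to defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the `yaml` package is required to read YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the `jsonlite` package is required to read JSON configs")
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("unsupported config format: .", ext)
  grid <- if (!is.null(raw$grid)) do.call(generate_grid, raw$grid)
          else generate_grid()
  raw$grid <- NULL
  known <- setdiff(names(formals(pipeline_config)), "grid")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, c(list(grid = grid), raw))
}

# Synthetic annual Δ-series (lat x lon x n_years): per-cell mean plus AR(1)
# interannual noise, used by the significance stage.
annual_difference_series <- function(mean_map, n_years, sd, ar1, seed) {
  set.seed(seed)
  nlat <- nrow(mean_map); nlon <- ncol(mean_map)
  ncell <- nlat * nlon
  innov_sd <- sd * sqrt(1 - ar1^2)
  e <- matrix(stats::rnorm(n_years * ncell, sd = innov_sd), nrow = n_years)
  noise <- apply(e, 2, function(x)
    as.numeric(stats::filter(x, ar1, method = "recursive")))
  arr <- array(0, dim = c(nlat, nlon, n_years))
  for (t in seq_len(n_years))
    arr[, , t] <- mean_map + matrix(noise[t, ], nlat, nlon)
  arr
}

region_mean_delta <- function(delta_map, grid, region_mask) {
  w <- grid$cell_area_ha
  regions <- attr(region_mask, "regions")
  eu <- sum(delta_map * w) / sum(w)
  out <- data.frame(region = "EU", value = eu, stringsAsFactors = FALSE)
  tot <- vapply(seq_along(regions), function(r) {
    sel <- region_mask == r
    sum(delta_map[sel] * w[sel]) / sum(w[sel])
  }, numeric(1))
  rbind(out, data.frame(region = regions, value = tot,
                        stringsAsFactors = FALSE))
}

run_family <- function(config, archetype, index) {
  grid <- config$grid
  scfg <- scenario_config(archetype,
                          n_policy_fraction = config$n_policy_fraction,
                          seed = config$seed + (index - 1L))
  pair <- generate_scenario_pair(grid, scfg)
  cw <- build_crosswalk(config$crosswalk_path,
                        model = archetype_model(archetype))
  coefs <- biodiversity_coefficients(config$coefficients_path)

  lay_b <- economic_to_predicts(pair$baseline, cw,
                                yield_map = pair$yield$baseline,
                                stocking_map = pair$stocking$baseline)
  lay_h <- economic_to_predicts(pair$halving, cw,
                                yield_map = pair$yield$halving,
                                stocking_map = pair$stocking$halving)
  bio_b <- project_biodiversity(lay_b, coefs)
  bio_h <- project_biodiversity(lay_h, coefs)

  pft_b <- economic_to_pft(pair$baseline, cw)
  pft_h <- economic_to_pft(pair$halving, cw)
  fld_b <- generate_carbon_fields(grid, pft_b, scfg)
  fld_h <- generate_carbon_fields(grid, pft_h, scfg)

  delta_eq <- scenario_difference(fld_h, fld_b)
  soil_b <- cell_total(fld_b, "soil")
  soil_h_eq <- cell_total(fld_h, "soil")
  d_soil <- soil_carbon_relaxation(soil_b, soil_h_eq, scfg$soil_tau,
                                   config$sim_years) - soil_b
  d_npp <- delta_eq$npp
  d_biomass <- delta_eq$biomass
  d_sr <- bio_h$sr - bio_b$sr
  d_bii <- bio_h$bii - bio_b$bii

  mask <- generate_region_mask(grid, config$n_regions)
  totals <- data.frame(
    region = aggregate_totals(d_npp, grid, mask)$region,
    d_npp_mtc_yr = aggregate_totals(d_npp, grid, mask)$total,
    d_soil_c_mtc = aggregate_totals(d_soil, grid, mask)$total,
    d_biomass_c_mtc = aggregate_totals(d_biomass, grid, mask)$total,
    d_bii_pp = region_mean_delta(d_bii, grid, mask)$value,
    d_sr_pp = region_mean_delta(d_sr, grid, mask)$value,
    stringsAsFactors = FALSE
  )

  series <- annual_difference_series(d_npp, config$n_years,
                                     config$npp_interannual_sd,
                                     config$npp_ar1,
                                     seed = config$seed + 500L + index)
  signif_mask <- significance_mask(series, config$alpha)

  breakdown <- list(
    soil = breakdown_by_landuse(
      carbon_breakdown_states(fld_b, fld_h, "soil",
                              horizon = config$sim_years,
                              tau = scfg$soil_tau),
      indicator = "soil_c_mtc"),
    npp = breakdown_by_landuse(
      carbon_breakdown_states(fld_b, fld_h, "npp"),
      indicator = "npp_mtc_yr"),
    sr = breakdown_by_landuse(
      sr_breakdown_states(lay_b, lay_h, coefs),
      indicator = "sr_pp")
  )

  quadrants <- quadrant_report(
    list(soil_c_vs_bii = classify_quadrants(d_soil, d_bii),
         soil_c_vs_sr = classify_quadrants(d_soil, d_sr)),
    family = archetype)

  list(archetype = archetype, scenario_config = scfg, pair = pair,
       biodiversity = list(baseline = bio_b, halving = bio_h),
       delta = list(npp = d_npp, soil = d_soil, biomass = d_biomass,
                    sr = d_sr, bii = d_bii),
       totals = totals, breakdown = breakdown, quadrants = quadrants,
       significance = signif_mask, region_mask = mask)
}

#' Run the full assessment pipeline
#'
#' Executes, for each configured scenario family: scenario generation,
#' crosswalks to biodiversity classes and PFTs, biodiversity projection for
#' both scenarios, carbon field generation and differencing (soil carbon
#' relaxed over the configured horizon), regional totals, the
#' serial-correlation-corrected significance mask for the annual NPP
#' difference series, the LMDI area/intensity breakdown for soil carbon,
#' NPP and species richness, and the Win/Loss quadrant classification.
#' Stages communicate only through their return values (one-way coupling);
#' a fixed seed makes the whole run deterministic.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `halven_run`: list with the `config` and one
#'   result set per family (see [run_pipeline()] internals), each holding
#'   the scenario pair, biodiversity maps, delta maps, `totals` (Table-3
#'   style region x indicator data frame), `breakdown` (LMDI tables),
#'   `quadrants` and the significance mask.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config")
  families <- list()
  for (i in seq_along(config$archetypes)) {
    a <- config$archetypes[i]
    families[[a]] <- tryCatch(
      run_family(config, a, i),
      error = function(e)
        stop("pipeline stage failed for family '", a, "': ",
             conditionMessage(e), call. = FALSE)
    )
  }
  run <- structure(list(config = config, families = families),
                   class = "halven_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.halven_run <- function(x, ...) {
  cat(sprintf("<halven_run> seed %d, %d x %d cells\n",
              x$config$seed, x$config$grid$nlat, x$config$grid$nlon))
  for (f in x$families) {
    eu <- f$totals[f$totals$region == "EU", ]
    cat(sprintf(
      "  %-16s EU: dNPP %+.2f MtC/yr, dSoilC %+.2f MtC, dSR %+.2f pp, dBII %+.2f pp\n",
      f$archetype, eu$d_npp_mtc_yr, eu$d_soil_c_mtc, eu$d_sr_pp, eu$d_bii_pp))
  }
  invisible(x)
}

#' @export
summary.halven_run <- function(object, ...) {
  print(object)
  for (f in object$families) {
    cat(sprintf("\n-- %s: soil-carbon LMDI breakdown (MtC) --\n",
                f$archetype))
    print(f$breakdown$soil, digits = 4)
    cat(sprintf("\n-- %s: quadrant shares (%% of grid points) --\n",
                f$archetype))
    qq <- f$quadrants
    print.data.frame(qq[qq$pair == "soil_c_vs_sr", ], row.names = FALSE,
                     digits = 4)
  }
  invisible(object)
}

#' Scenario differences from a table of per-scenario levels
#'
#' Given EU-scale annual-mean indicator levels per scenario, emits the
#' Halving-N minus Baseline difference per indicator (the arithmetic behind
#' a Table-3-style summary row).
#'
#' @param levels Data frame with columns `indicator`, `baseline`,
#'   `halving_n` and optionally `family`.
#' @return The input with a `difference` column appended.
#' @export
tables_from_levels <- function(levels) {
  needed <- c("indicator", "baseline", "halving_n")
  miss <- setdiff(needed, names(levels))
  if (length(miss))
    stop("`levels` is missing column(s): ", paste(miss, collapse = ", "))
  levels$difference <- levels$halving_n - levels$baseline
  levels
}

#' Packaged EU-scale indicator levels per scenario family
#'
#' Loads the shipped per-scenario annual-mean EU levels (BII %, SR %, NPP
#' MtC/yr, soil and biomass carbon MtC) for the abandonment and
#' extensification families.
#'
#' @param path Optional CSV path overriding the packaged table.
#' @return Data frame with columns `family`, `indicator`, `baseline`,
#'   `halving_n`.
#' @export
eu_indicator_levels <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "eu_indicator_levels.csv",
                        package = "halven")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a pipeline run to CSV files
#'
#' Writes, per scenario family: the regional totals table, the three LMDI
#' breakdown tables, the quadrant report, and optionally the per-cell
#' scatter data (soil-carbon change vs biodiversity changes). Every file
#' carries metadata header lines (`# key: value`) recording the seed, the
#' family and the package version, so outputs are reproducible and
#' self-describing. Repeated runs with one seed produce byte-identical
#' files.
#'
#' @param run A `halven_run`.
#' @param dir Output directory (created if needed).
#' @param scatter Also dump per-cell (d_soil, d_bii, d_sr) tables.
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir, scatter = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  meta <- function(family) c(
    sprintf("# package: halven %s",
            as.character(utils::packageVersion("halven"))),
    sprintf("# seed: %d", run$config$seed),
    sprintf("# family: %s", family))
  emit <- function(df, name, family) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(meta(family), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    written <<- c(written, path)
  }
  for (f in run$families) {
    emit(f$totals, sprintf("totals_%s.csv", f$archetype), f$archetype)
    for (ind in names(f$breakdown))
      emit(as.data.frame(f$breakdown[[ind]]),
           sprintf("breakdown_%s_%s.csv", ind, f$archetype), f$archetype)
    emit(f$quadrants, sprintf("quadrants_%s.csv", f$archetype), f$archetype)
    if (scatter) {
      sc <- data.frame(d_soil_c = as.vector(f$delta$soil),
                       d_bii = as.vector(f$delta$bii),
                       d_sr = as.vector(f$delta$sr))
      emit(sc, sprintf("scatter_%s.csv", f$archetype), f$archetype)
    }
  }
  invisible(written)
}
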