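test_that("yield response is a saturating curve with the expected anchors", {
  expect_equal(nitrogen_yield_response(0, 2, 8, 100), 2)
  expect_equal(nitrogen_yield_response(100, 2, 8, 100), 5)  # half saturation
  expect_equal(nitrogen_yield_response(150, 2, 8, 100), 5.6)
  expect_error(nitrogen_yield_response(-1), "non-negative")
  expect_error(nitrogen_yield_response(10, y_min = 5, y_max = 4), "y_min")
  expect_error(nitrogen_yield_response(10, k_half = 0), "k_half")
  # strictly increasing, concave
  n <- seq(0, 400, by = 10)
  y <- nitrogen_yield_response(n)
  expect_true(all(diff(y) > 0))
  expect_true(all(diff(diff(y)) < 0))
})

test_that("gaussian random field is reproducible and autocorrelated at the
           configured range", {
  set.seed(11); f1 <- gaussian_random_field(60, 60, range_cells = 3)
  set.seed(11); f2 <- gaussian_random_field(60, 60, range_cells = 3)
  expect_identical(f1, f2)
  expect_equal(stats::var(as.vector(f1)), 1, tolerance = 0.35)

  # empirical semivariogram along rows: rises then flattens near the sill
  semivar <- function(f, lag) {
    d <- f[, seq_len(ncol(f) - lag)] - f[, (lag + 1):ncol(f)]
    mean(d^2) / 2
  }
  set.seed(42)
  f <- gaussian_random_field(120, 120, range_cells = 3)
  sill <- stats::var(as.vector(f))
  expect_lt(semivar(f, 1), 0.5 * sill)           # short lags still correlated
  expect_equal(semivar(f, 12), sill, tolerance = 0.25)  # flat beyond ~4 ranges
  expect_equal(semivar(f, 20), sill, tolerance = 0.25)
})

test_that("scenario pairs are closed, reproducible, and archetype-correct", {
  g <- tiny_grid(6, 6)
  for (arch in c("abandonment", "extensification")) {
    cfg <- scenario_config(arch, seed = 3)
    pair <- generate_scenario_pair(g, cfg)
    for (m in list(pair$baseline, pair$halving)) {
      sums <- apply(m$fractions, c(1, 2), sum)
      expect_lt(max(abs(sums - 1)), 1e-9)
      expect_true(all(m$fractions >= 0 & m$fractions <= 1))
    }
    pair2 <- generate_scenario_pair(g, cfg)
    expect_identical(pair$halving$fractions, pair2$halving$fractions)

    cw <- build_crosswalk(model = halven:::archetype_model(arch))
    crops <- halven:::crop_categories(cw, include_fallow = FALSE)
    a_b <- category_areas_mha(pair$baseline)
    a_h <- category_areas_mha(pair$halving)
    crop_cats <- intersect(crops, names(a_b))
    if (arch == "abandonment") {
      expect_lt(sum(a_h[crop_cats]), sum(a_b[crop_cats]))
      grassy <- intersect(c("Fallow", "Pasture", "Rangeland"), names(a_b))
      expect_gt(sum(a_h[grassy]), sum(a_b[grassy]))
    } else {
      expect_gt(sum(a_h[crop_cats]), sum(a_b[crop_cats]))
      expect_lt(a_h[["Pasture"]], a_b[["Pasture"]])
      # policy yields are lower everywhere than baseline yields
      expect_true(all(pair$yield$halving < pair$yield$baseline))
    }
  }
})

test_that("no policy means no land-use change", {
  g <- tiny_grid(3, 3)
  cfg <- scenario_config("abandonment", n_policy_fraction = 1, seed = 5)
  pair <- generate_scenario_pair(g, cfg)
  expect_identical(pair$baseline$fractions, pair$halving$fractions)
  expect_identical(pair$yield$baseline, pair$yield$halving)
})

test_that("scenario configuration is validated", {
  expect_error(scenario_config("terraforming"), "arg")
  expect_error(scenario_config(n_policy_fraction = 0), "n_policy_fraction")
  expect_error(scenario_config(n_policy_fraction = 1.5), "n_policy_fraction")
  expect_error(scenario_config(soil_tau = -1), "soil_tau")
  expect_error(scenario_config(y_min = 9, y_max = 8), "y_min")
})

test_that("carbon fields honor means, seeds and positivity", {
  g <- tiny_grid(3, 3)
  cfg <- scenario_config("abandonment", seed = 2)
  pair <- generate_scenario_pair(g, cfg)
  cw <- build_crosswalk(model = "AROPAj")
  pft <- economic_to_pft(pair$baseline, cw)

  # zero noise: densities equal the configured means exactly
  f0 <- generate_carbon_fields(g, pft, cfg,
                               noise_sd = c(npp = 0, soil = 0, biomass = 0))
  means <- carbon_means()
  for (p in dimnames(f0$soil)[[3]])
    expect_equal(unique(as.vector(f0$soil[, , p])),
                 means$soil[means$pft == p])

  f1 <- generate_carbon_fields(g, pft, cfg)
  f2 <- generate_carbon_fields(g, pft, cfg)
  expect_identical(f1$soil, f2$soil)
  expect_true(all(f1$soil > 0) && all(f1$npp > 0) && all(f1$biomass > 0))
  expect_error(carbon_means(soil = c(c3_natural_grass = -5)), "non-negative")

  # default ordering: grass and forest soils hold more carbon than cropland
  crop_soil <- means$soil[means$pft %in% halven:::CROP_PFTS]
  other_soil <- means$soil[means$pft %in% c(halven:::GRASS_PFTS,
                                            halven:::FOREST_PFTS)]
  expect_true(max(crop_soil) < min(other_soil))
})

test_that("soil carbon relaxes exponentially toward equilibrium", {
  expect_equal(soil_carbon_relaxation(100, 200, 40, 0), 100)
  expect_equal(soil_carbon_relaxation(100, 200, 40, 40), 200 - 100 * exp(-1))
  expect_equal(soil_carbon_relaxation(100, 200, 40, 40), 163.212,
               tolerance = 1e-5)
  expect_equal(soil_carbon_relaxation(100, 200, 40, 50 * 40), 200,
               tolerance = 1e-6)
  expect_error(soil_carbon_relaxation(1, 2, 0, 10), "tau")
  expect_error(soil_carbon_relaxation(1, 2, 10, -1), "t_years")
  # monotone approach
  t <- seq(0, 300, by = 10)
  c_t <- soil_carbon_relaxation(100, 200, 40, t)
  expect_true(all(diff(c_t) > 0) && all(c_t <= 200))
})
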