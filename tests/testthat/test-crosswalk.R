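test_that("default crosswalk encodes the published correspondences", {
  nlu <- build_crosswalk(model = "NLU")
  expect_equal(nlu$predicts$class[nlu$predicts$category == "Maize"], "annual")
  expect_equal(nlu$pft$pft[nlu$pft$category == "Maize"], "c4_summer_crop")
  expect_setequal(nlu$predicts$class[nlu$predicts$category == "Soybean"],
                  "nfixing")

  ar <- build_crosswalk(model = "AROPAj")
  fallow <- ar$predicts[ar$predicts$category == "Fallow", ]
  expect_equal(fallow$class, "annual")
  expect_equal(fallow$intensity_rule, "minimal")
  expect_equal(ar$pft$pft[ar$pft$category == "Fallow"], "c3_natural_grass")
  expect_setequal(ar$predicts$class[ar$predicts$category == "Forest"],
                  c("primary", "secondary"))
})

test_that("crosswalk validation rejects malformed tables", {
  bad_dup <- write_temp_csv(c(
    "model,category,target_model,target_class,intensity_rule,split_group,split_fraction",
    "AROPAj,Maize,PREDICTS,annual,yield_shares,,1",
    "AROPAj,Maize,PREDICTS,annual,yield_shares,,1",
    "AROPAj,Maize,PFT,c4_summer_crop,,,1"))
  expect_error(build_crosswalk(bad_dup, model = "AROPAj"), "duplicate")

  bad_split <- write_temp_csv(c(
    "model,category,target_model,target_class,intensity_rule,split_group,split_fraction",
    "AROPAj,Forest,PREDICTS,primary,none,ps,0.5",
    "AROPAj,Forest,PREDICTS,secondary,none,ps,0.4",
    "AROPAj,Forest,PFT,forest_broadleaf_evergreen,,,1"))
  expect_error(build_crosswalk(bad_split, model = "AROPAj"), "sum to 1")

  g <- tiny_grid(1, 1)
  cw <- build_crosswalk(model = "AROPAj")
  kelp <- uniform_landuse_map(c("Martian kelp" = 1), g)
  expect_error(economic_to_pft(kelp, cw), "unknown economic land-use")
})

test_that("fallow maps entirely to minimal-intensity annual cropland", {
  g <- tiny_grid(1, 1)
  cw <- build_crosswalk(model = "AROPAj")
  m <- uniform_landuse_map(c(Fallow = 1), g)
  lay <- economic_to_predicts(m, cw)  # no yield needed: fallow is not yield-driven
  expect_equal(unname(lay$fractions[1, 1, "annual_minimal"]), 1)
  expect_equal(sum(lay$fractions[1, 1, ]), 1)
})

test_that("yield-driven cropland categories pass the share model through", {
  g <- tiny_grid(1, 1)
  cw <- build_crosswalk(model = "AROPAj")
  m <- uniform_landuse_map(c("Tender wheat" = 1), g)
  sm <- intensity_share_model(c(3, 6), 1)
  y <- matrix(4.5, 1, 1)
  lay <- economic_to_predicts(m, cw, share_model = sm, yield_map = y)
  sh <- intensity_shares(4.5, sm)
  expect_equal(unname(lay$fractions[1, 1, "annual_minimal"]), sh$minimal)
  expect_equal(unname(lay$fractions[1, 1, "annual_light"]), sh$light)
  expect_equal(unname(lay$fractions[1, 1, "annual_intense"]), sh$intense)
  # yield missing where cropland present is an error
  expect_error(economic_to_predicts(m, cw), "yield_map")
})

test_that("forest splits between primary and secondary by the configured fraction", {
  g <- tiny_grid(1, 1)
  cw <- build_crosswalk(model = "AROPAj")
  m <- uniform_landuse_map(c(Forest = 0.5, Urban = 0.5), g)
  lay <- economic_to_predicts(m, cw)
  expect_equal(unname(lay$fractions[1, 1, "primary"]), 0.25)   # default 0.5/0.5 split
  expect_equal(unname(lay$fractions[1, 1, "secondary"]), 0.25)

  custom <- write_temp_csv(c(
    "model,category,target_model,target_class,intensity_rule,split_group,split_fraction",
    "AROPAj,Forest,PREDICTS,primary,none,ps,0.4",
    "AROPAj,Forest,PREDICTS,secondary,none,ps,0.6",
    "AROPAj,Forest,PFT,forest_broadleaf_evergreen,,,1",
    "AROPAj,Urban,PREDICTS,urban,none,,1",
    "AROPAj,Urban,PFT,bare_soil,,,1"))
  cw2 <- build_crosswalk(custom, model = "AROPAj")
  lay2 <- economic_to_predicts(m, cw2)
  expect_equal(unname(lay2$fractions[1, 1, "primary"]), 0.20)
  expect_equal(unname(lay2$fractions[1, 1, "secondary"]), 0.30)
})

test_that("PFT crosswalk reproduces the published rows and conserves area", {
  g <- tiny_grid(1, 1)
  nlu <- build_crosswalk(model = "NLU")
  m <- uniform_landuse_map(c(Rapeseed = 0.5, Sunflower = 0.5), g, model = "NLU")
  pft <- economic_to_pft(m, nlu)
  expect_equal(unname(pft$fractions[1, 1, "c3_winter_crop"]), 0.5)
  expect_equal(unname(pft$fractions[1, 1, "c3_summer_crop"]), 0.5)

  urb <- uniform_landuse_map(c(Urban = 1), g, model = "NLU")
  expect_equal(unname(economic_to_pft(urb, nlu)$fractions[1, 1, "bare_soil"]), 1)

  # vacuous input: zero categories, zero fractions, no error
  empty <- landuse_map(array(0, dim = c(1, 1, 0),
                             dimnames = list(NULL, NULL, character())),
                       g, "baseline", "NLU")
  lay <- economic_to_pft(empty, nlu)
  expect_true(all(lay$fractions == 0))
})

test_that("crosswalk conserves every category's area through both targets", {
  g <- tiny_grid(2, 2)
  for (model in c("AROPAj", "NLU")) {
    cw <- build_crosswalk(model = model)
    y <- matrix(5, g$nlat, g$nlon)
    for (cat in cw$categories) {
      m <- uniform_landuse_map(stats::setNames(1, cat), g, model = model)
      a_cat <- sum(g$cell_area_ha)
      pft <- economic_to_pft(m, cw)
      expect_equal(sum(sweep(pft$fractions, c(1, 2), g$cell_area_ha, "*")),
                   a_cat, tolerance = 1e-12)
      lay <- economic_to_predicts(m, cw, yield_map = y)
      expect_equal(sum(sweep(lay$fractions, c(1, 2), g$cell_area_ha, "*")),
                   a_cat, tolerance = 1e-12)
    }
  }
})

test_that("crosswalked layers inherit closure from closed inputs", {
  g <- tiny_grid(4, 4)
  pair <- generate_scenario_pair(g, scenario_config("extensification", seed = 9))
  cw <- build_crosswalk(model = "NLU")
  lay <- economic_to_predicts(pair$halving, cw,
                              yield_map = pair$yield$halving,
                              stocking_map = pair$stocking$halving)
  expect_lt(max(abs(apply(lay$fractions, c(1, 2), sum) - 1)), 1e-9)
  pft <- economic_to_pft(pair$halving, cw)
  expect_lt(max(abs(apply(pft$fractions, c(1, 2), sum) - 1)), 1e-9)
})
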