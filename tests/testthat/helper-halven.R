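# Shared fixtures: tiny grids, hand-built layers and fields.

tiny_grid <- function(nlat = 4, nlon = 4, res = 0.5) {
  generate_grid(45, 45 + nlat * res, 5, 5 + nlon * res, resolution = res)
}

predicts_class_names <- function() halven:::PREDICTS_CLASSES
pft_class_names <- function() halven:::PFT_CLASSES

# A predicts_layer with the same named fraction vector in every cell.
uniform_predicts_layer <- function(fracs, grid = tiny_grid(1, 1)) {
  classes <- predicts_class_names()
  stopifnot(all(names(fracs) %in% classes))
  arr <- array(0, dim = c(grid$nlat, grid$nlon, length(classes)),
               dimnames = list(NULL, NULL, classes))
  for (nm in names(fracs)) arr[, , nm] <- fracs[[nm]]
  halven:::predicts_layer(arr, grid)
}

# A predicts_layer with independent random closed compositions per cell.
random_predicts_layer <- function(grid = tiny_grid(), seed = 1) {
  set.seed(seed)
  classes <- predicts_class_names()
  arr <- array(stats::rgamma(grid$nlat * grid$nlon * length(classes), 1),
               dim = c(grid$nlat, grid$nlon, length(classes)),
               dimnames = list(NULL, NULL, classes))
  sums <- apply(arr, c(1, 2), sum)
  halven:::predicts_layer(sweep(arr, c(1, 2), sums, "/"), grid)
}

# A landuse_map with the same named composition in every cell.
uniform_landuse_map <- function(fracs, grid = tiny_grid(1, 1),
                                model = "AROPAj", scenario = "baseline") {
  arr <- array(0, dim = c(grid$nlat, grid$nlon, length(fracs)),
               dimnames = list(NULL, NULL, names(fracs)))
  for (nm in names(fracs)) arr[, , nm] <- fracs[[nm]]
  landuse_map(arr, grid, scenario, model)
}

# Minimal hand-built carbon_fields: one PFT, constant densities.
constant_fields <- function(grid, soil = 100, npp = 4, biomass = 10,
                            pft = "c3_natural_grass", fraction = 1) {
  mk <- function(v) array(v, dim = c(grid$nlat, grid$nlon, 1),
                          dimnames = list(NULL, NULL, pft))
  structure(list(soil = mk(soil), npp = mk(npp), biomass = mk(biomass),
                 fractions = mk(fraction), grid = grid),
            class = "carbon_fields")
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
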