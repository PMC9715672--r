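# Canonical class vocabularies shared across modules: land-surface-model
# plant functional types and biodiversity land-use x intensity classes.

PFT_CLASSES <- c(
  "c3_winter_crop", "c3_summer_crop", "c4_summer_crop",
  "c3_natural_grass", "c4_natural_grass",
  "forest_needleleaf_evergreen", "forest_broadleaf_evergreen",
  "forest_needleleaf_summergreen", "forest_broadleaf_summergreen",
  "bare_soil"
)
CROP_PFTS   <- c("c3_winter_crop", "c3_summer_crop", "c4_summer_crop")
GRASS_PFTS  <- c("c3_natural_grass", "c4_natural_grass")
FOREST_PFTS <- grep("^forest_", PFT_CLASSES, value = TRUE)

PREDICTS_TARGETS <- c("primary", "secondary", "annual", "perennial",
                      "nfixing", "pasture", "rangeland", "urban")
CROP_GROUPS <- c("annual", "perennial", "nfixing")
CROP_INTENSITIES <- c("minimal", "light", "intense")

PREDICTS_CLASSES <- c(
  "primary", "secondary",
  paste0(rep(CROP_GROUPS, each = 3), "_", CROP_INTENSITIES),
  "pasture_light", "pasture_intense",
  "rangeland", "urban"
)
PREDICTS_CROP_CLASSES <- grep("^(annual|perennial|nfixing)_",
                              PREDICTS_CLASSES, value = TRUE)

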