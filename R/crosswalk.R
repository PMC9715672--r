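# Crosswalk between economic-model land-use categories, biodiversity
# land-use x intensity classes, and land-surface-model plant functional types.

#' Load and validate a land-use crosswalk table
#'
#' Reads the correspondence between an economic model's land-use categories
#' and (a) the biodiversity model's land-use classes with their intensity
#' rule, (b) the land-surface-model plant functional types (PFTs). Each
#' category may split over several targets (e.g. Forest into primary and
#' secondary vegetation, Pasture into C3 and C4 natural grass); split
#' fractions must sum to one per category and target model so that area is
#' conserved exactly.
#'
#' The packaged default table covers the two economic models emulated by the
#' scenario generator: a supply-side model with explicit fallow (the
#' abandonment archetype) and a partial-equilibrium model (the
#' extensification archetype). Fallow is mapped to minimal-intensity annual
#' cropland for biodiversity and to natural grass for carbon. The supply-side
#' "Perennial" category carries no printed PFT correspondence; it is mapped
#' to C3 natural grass so that per-cell fractions stay closed.
#'
#' @param path CSV file with columns `model, category, target_model,
#'   target_class, intensity_rule, split_group, split_fraction`; `NULL` loads
#'   the packaged default.
#' @param model Which economic model's rows to use, `"AROPAj"` or `"NLU"`.
#' @return An object of class `crosswalk`: list with elements `model`,
#'   `categories`, `predicts` (data frame category/class/intensity_rule/
#'   weight) and `pft` (data frame category/pft/weight).
#' @export
build_crosswalk <- function(path = NULL, model = c("AROPAj", "NLU")) {
  model <- match.arg(model)
  if (is.null(path))
    path <- system.file("extdata", "crosswalk_table.csv", package = "halven")
  if (!file.exists(path)) stop("crosswalk table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("model", "category", "target_model", "target_class",
              "intensity_rule", "split_fraction")
  if (!all(needed %in% names(raw)))
    stop("crosswalk table is missing columns: ",
         paste(setdiff(needed, names(raw)), collapse = ", "))
  raw <- raw[raw$model == model, , drop = FALSE]
  if (nrow(raw) == 0) stop("no crosswalk rows for model ", model)

  dup <- duplicated(raw[c("category", "target_model", "target_class")])
  if (any(dup))
    stop("duplicate crosswalk entries for: ",
         paste(unique(raw$category[dup]), collapse = ", "))

  pr <- raw[raw$target_model == "PREDICTS", , drop = FALSE]
  pf <- raw[raw$target_model == "PFT", , drop = FALSE]
  bad_pr <- setdiff(pr$target_class, PREDICTS_TARGETS)
  if (length(bad_pr)) stop("unknown PREDICTS target class: ",
                           paste(bad_pr, collapse = ", "))
  bad_pf <- setdiff(pf$target_class, PFT_CLASSES)
  if (length(bad_pf)) stop("unknown PFT class: ",
                           paste(bad_pf, collapse = ", "))

  cats <- sort(unique(raw$category))
  for (tab in list(pr, pf)) {
    s <- tapply(tab$split_fraction, tab$category, sum)
    if (!setequal(names(s), cats))
      stop("every category must map to both a PREDICTS class and a PFT")
    if (any(abs(s - 1) > 1e-9))
      stop("split fractions do not sum to 1 for: ",
           paste(names(s)[abs(s - 1) > 1e-9], collapse = ", "))
  }

  structure(
    list(
      model = model,
      categories = cats,
      predicts = data.frame(category = pr$category, class = pr$target_class,
                            intensity_rule = pr$intensity_rule,
                            weight = pr$split_fraction,
                            stringsAsFactors = FALSE),
      pft = data.frame(category = pf$category, pft = pf$target_class,
                       weight = pf$split_fraction, stringsAsFactors = FALSE)
    ),
    class = "crosswalk"
  )
}

#' @export
print.crosswalk <- function(x, ...) {
  cat(sprintf("<crosswalk> %s: %d categories -> %d PREDICTS targets, %d PFTs\n",
              x$model, length(x$categories),
              length(unique(x$predicts$class)),
              length(unique(x$pft$pft))))
  invisible(x)
}

# Categories whose biodiversity intensity is yield-driven (croplands
# excluding fallow, which is pinned to minimal intensity).
crop_categories <- function(cw, include_fallow = FALSE) {
  rules <- if (include_fallow) c("yield_shares", "minimal") else "yield_shares"
  sort(unique(cw$predicts$category[cw$predicts$intensity_rule %in% rules]))
}

check_known_categories <- function(map_categories, cw) {
  unknown <- setdiff(map_categories, cw$categories)
  if (length(unknown))
    stop("unknown economic land-use category: ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Crosswalk an economic land-use map to biodiversity land-use classes
#'
#' Converts per-cell fractions over economic categories into fractions over
#' the biodiversity model's land-use x intensity classes. Cropland categories
#' are split over minimal/light/intense via the yield-driven share model;
#' fallow is forced to minimal-intensity annual cropland; pasture is split
#' over light/intense by a stocking-rate-driven share model; forest and other
#' natural areas are split between primary and secondary vegetation by the
#' crosswalk's split fractions. Per-cell closure (sum to 1) is preserved
#' exactly because every split and every share vector sums to one.
#'
#' @param map A `landuse_map`.
#' @param cw A `crosswalk` for the map's economic model.
#' @param share_model Crop intensity share model, see
#'   [intensity_share_model()].
#' @param yield_map Per-cell yield (tDM/ha) matrix; required wherever a
#'   yield-driven cropland category has positive fraction.
#' @param stocking_map Per-cell stocking proxy (heads/ha); defaults to 1
#'   everywhere.
#' @param pasture_model Pasture intensity share model, see
#'   [pasture_share_model()].
#' @return A `predicts_layer`: 3-d array (lat x lon x class) with an attached
#'   grid.
#' @export
economic_to_predicts <- function(map, cw,
                                 share_model = intensity_share_model(),
                                 yield_map = NULL,
                                 stocking_map = NULL,
                                 pasture_model = pasture_share_model()) {
  fr <- map$fractions
  nlat <- dim(fr)[1]; nlon <- dim(fr)[2]
  cats <- dimnames(fr)[[3]]
  check_known_categories(cats, cw)
  out <- array(0, dim = c(nlat, nlon, length(PREDICTS_CLASSES)),
               dimnames = list(NULL, NULL, PREDICTS_CLASSES))
  if (length(cats) == 0)
    return(predicts_layer(out, map$grid, map$scenario))

  if (is.null(stocking_map)) stocking_map <- matrix(1, nlat, nlon)

  crop_shares <- NULL
  need_yield <- intersect(cats, crop_categories(cw))
  if (length(need_yield)) {
    if (is.null(yield_map)) {
      has_crop <- apply(fr[, , need_yield, drop = FALSE], c(1, 2), sum) > 0
      if (any(has_crop))
        stop("`yield_map` is required where cropland fraction is positive")
    } else {
      crop_shares <- intensity_shares(yield_map, share_model)
    }
  }
  past_shares <- pasture_shares(stocking_map, pasture_model)

  rows <- cw$predicts[cw$predicts$category %in% cats, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    f <- fr[, , rows$category[i]] * rows$weight[i]
    cls <- rows$class[i]
    rule <- rows$intensity_rule[i]
    if (cls %in% c("primary", "secondary", "rangeland", "urban")) {
      out[, , cls] <- out[, , cls] + f
    } else if (cls == "pasture") {
      out[, , "pasture_light"] <- out[, , "pasture_light"] + f * past_shares$light
      out[, , "pasture_intense"] <- out[, , "pasture_intense"] + f * past_shares$intense
    } else if (rule == "minimal") {
      key <- paste0(cls, "_minimal")
      out[, , key] <- out[, , key] + f
    } else if (rule == "yield_shares") {
      if (is.null(crop_shares) && any(f > 0))
        stop("`yield_map` is required where cropland fraction is positive")
      for (lev in CROP_INTENSITIES) {
        key <- paste0(cls, "_", lev)
        out[, , key] <- out[, , key] + f * crop_shares[[lev]]
      }
    } else {
      stop("unhandled intensity rule '", rule, "' for class ", cls)
    }
  }
  predicts_layer(out, map$grid, map$scenario)
}

#' Crosswalk an economic land-use map to plant functional types
#'
#' Sums economic category fractions into PFT bins using the crosswalk's
#' split fractions; per-cell closure is preserved exactly.
#'
#' @inheritParams economic_to_predicts
#' @return A `pft_layer`: 3-d array (lat x lon x PFT) with attached grid.
#' @export
economic_to_pft <- function(map, cw) {
  fr <- map$fractions
  nlat <- dim(fr)[1]; nlon <- dim(fr)[2]
  cats <- dimnames(fr)[[3]]
  check_known_categories(cats, cw)
  out <- array(0, dim = c(nlat, nlon, length(PFT_CLASSES)),
               dimnames = list(NULL, NULL, PFT_CLASSES))
  rows <- cw$pft[cw$pft$category %in% cats, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    p <- rows$pft[i]
    out[, , p] <- out[, , p] + fr[, , rows$category[i]] * rows$weight[i]
  }
  pft_layer(out, map$grid, map$scenario)
}

predicts_layer <- function(fractions, grid, scenario = NULL) {
  structure(list(fractions = fractions, grid = grid, scenario = scenario),
            class = "predicts_layer")
}

pft_layer <- function(fractions, grid, scenario = NULL) {
  structure(list(fractions = fractions, grid = grid, scenario = scenario),
            class = "pft_layer")
}

#' @export
print.predicts_layer <- function(x, ...) {
  cat(sprintf("<predicts_layer> %d x %d cells, %d classes%s\n",
              dim(x$fractions)[1], dim(x$fractions)[2], dim(x$fractions)[3],
              if (!is.null(x$scenario)) paste0(" [", x$scenario, "]") else ""))
  invisible(x)
}

#' @export
print.pft_layer <- function(x, ...) {
  cat(sprintf("<pft_layer> %d x %d cells, %d PFTs%s\n",
              dim(x$fractions)[1], dim(x$fractions)[2], dim(x$fractions)[3],
              if (!is.null(x$scenario)) paste0(" [", x$scenario, "]") else ""))
  invisible(x)
}
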