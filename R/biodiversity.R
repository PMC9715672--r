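# Projection of biodiversity indicators (species richness, total abundance,
# compositional similarity, BII) from land-use x intensity fraction layers,
# all expressed relative to the primary-vegetation reference.

#' Load and validate biodiversity model coefficients
#'
#' Coefficients are supplied per land-use x intensity class on the scales the
#' underlying mixed-effects models were fitted on: log scale for species
#' richness (Poisson link), square-root scale for within-study-rescaled total
#' abundance, and adjusted-logit scale for the asymmetric Jaccard
#' compositional similarity to primary-vegetation baseline sites. The
#' similarity coefficients must be coarsened: equal across intensities for
#' every class except perennial cropland. The packaged default set is
#' synthetic (not fitted to survey data) and respects the qualitative
#' ordering primary >= secondary >= pasture >= cropland for species richness.
#'
#' @param path CSV with columns `class, intensity, sr_coef, abundance_coef,
#'   similarity_coef` (intensity `"none"` for classes without intensity
#'   levels); `NULL` loads the packaged synthetic defaults.
#' @return Object of class `biodiversity_coefficients`: data frame keyed by
#'   the layer class name (`key` column), one row per projected class.
#' @export
biodiversity_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "biodiversity_coefficients_synthetic.csv",
                        package = "halven")
  if (!file.exists(path)) stop("coefficient file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("class", "intensity", "sr_coef", "abundance_coef",
              "similarity_coef")
  if (!all(needed %in% names(df)))
    stop("coefficient file is missing columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  df$key <- ifelse(df$intensity == "none", df$class,
                   paste(df$class, df$intensity, sep = "_"))
  if (anyDuplicated(df$key))
    stop("duplicate coefficient rows: ",
         paste(df$key[duplicated(df$key)], collapse = ", "))
  miss <- setdiff(PREDICTS_CLASSES, df$key)
  if (length(miss))
    stop("missing coefficients for class: ", paste(miss, collapse = ", "))
  if (!"primary" %in% df$key) stop("reference class `primary` is required")
  # Coarsening: similarity may vary with intensity only for perennial crops.
  for (cl in setdiff(unique(df$class), "perennial")) {
    v <- df$similarity_coef[df$class == cl]
    if (length(v) > 1 && max(v) - min(v) > 1e-12)
      stop("similarity coefficients must be intensity-invariant for class ",
           cl, " (coarsening rule)")
  }
  rownames(df) <- df$key
  structure(df, class = c("biodiversity_coefficients", "data.frame"))
}

coef_lookup <- function(coefs, keys, column) {
  idx <- match(keys, coefs$key)
  if (anyNA(idx))
    stop("missing coefficient for class: ",
         paste(keys[is.na(idx)], collapse = ", "))
  coefs[[column]][idx]
}

#' Back-transform an adjusted-logit similarity coefficient to the data scale
#'
#' Inverts the symmetric adjustment used before the logit transform:
#' `s = (plogis(x) - epsilon) / (1 - 2 epsilon)`, clipped to \[0, 1\].
#'
#' @param x Coefficient(s) on the adjusted-logit scale.
#' @param epsilon Adjustment, default 0.01.
#' @export
similarity_from_logit <- function(x, epsilon = 0.01) {
  pmin(pmax((stats::plogis(x) - epsilon) / (1 - 2 * epsilon), 0), 1)
}

layer_fractions <- function(layer) {
  if (inherits(layer, "predicts_layer")) layer$fractions
  else if (is.array(layer) && length(dim(layer)) == 3) layer
  else stop("`layer` must be a predicts_layer or a 3-d fraction array")
}

# Fraction-weighted sum of per-class relative values, as a percentage.
project_weighted <- function(layer, rel) {
  fr <- layer_fractions(layer)
  keys <- dimnames(fr)[[3]]
  out <- matrix(0, dim(fr)[1], dim(fr)[2])
  for (k in seq_along(keys)) out <- out + fr[, , k] * rel[k]
  100 * out
}

#' Project relative species richness
#'
#' Per class, relative SR is `exp(sr_coef - sr_coef[primary])` (Poisson log
#' link); the cell value is 100 times the fraction-weighted sum, i.e. SR as a
#' percentage of the primary-vegetation level. A cell of 100% primary
#' vegetation scores exactly 100.
#'
#' @param layer A `predicts_layer` (closed per-cell fractions).
#' @param coefs A [biodiversity_coefficients()] object.
#' @return Matrix of SR% values.
#' @export
project_relative_sr <- function(layer, coefs) {
  keys <- dimnames(layer_fractions(layer))[[3]]
  sr <- coef_lookup(coefs, keys, "sr_coef")
  sr0 <- coef_lookup(coefs, "primary", "sr_coef")
  project_weighted(layer, exp(sr - sr0))
}

#' Project relative total abundance
#'
#' Per class, relative abundance is the squared ratio of the square-root-
#' scale predictions, `(abundance_coef / abundance_coef[primary])^2`; the
#' cell value is 100 times the fraction-weighted sum.
#'
#' @inheritParams project_relative_sr
#' @return Matrix of abundance% values.
#' @export
project_relative_abundance <- function(layer, coefs) {
  keys <- dimnames(layer_fractions(layer))[[3]]
  ab <- coef_lookup(coefs, keys, "abundance_coef")
  ab0 <- coef_lookup(coefs, "primary", "abundance_coef")
  if (ab0 <= 0)
    stop("square-root-scale abundance prediction for primary must be positive")
  project_weighted(layer, (ab / ab0)^2)
}

#' Project relative compositional similarity
#'
#' Per class, the adjusted-logit coefficient is back-transformed with
#' [similarity_from_logit()] and expressed relative to the primary class's
#' value; the cell value is 100 times the fraction-weighted sum. Similarity
#' coefficients are coarsened (validated at load time): intensity matters
#' only for perennial crops.
#'
#' @inheritParams project_relative_sr
#' @param epsilon Logit adjustment, default 0.01.
#' @return Matrix of similarity% values.
#' @export
project_compositional_similarity <- function(layer, coefs, epsilon = 0.01) {
  keys <- dimnames(layer_fractions(layer))[[3]]
  s <- similarity_from_logit(coef_lookup(coefs, keys, "similarity_coef"),
                             epsilon)
  s0 <- similarity_from_logit(coef_lookup(coefs, "primary", "similarity_coef"),
                              epsilon)
  if (s0 <= 0) stop("primary-vegetation similarity is zero; cannot normalize")
  project_weighted(layer, s / s0)
}

#' Biodiversity Intactness Index from abundance and similarity maps
#'
#' BII% is the product of the relative-abundance and relative-similarity
#' maps: `bii = abundance * similarity / 100`, so an intact cell (100, 100)
#' scores 100.
#'
#' @param abundance,similarity Matrices (%) on the same grid.
#' @return Matrix of BII% values.
#' @export
compute_bii <- function(abundance, similarity) {
  if (!identical(dim(abundance), dim(similarity)))
    stop("abundance and similarity maps are not on the same grid")
  abundance * similarity / 100
}

#' Project all biodiversity indicators for a land-use layer
#'
#' Convenience wrapper returning SR%, abundance%, similarity% and BII% maps.
#' Abundance and similarity are aggregated to the cell separately (fraction-
#' weighted means of class-level relative values) and then multiplied.
#'
#' @inheritParams project_compositional_similarity
#' @return Object of class `biodiversity_maps`: list of matrices `sr`,
#'   `abundance`, `similarity`, `bii`.
#' @export
project_biodiversity <- function(layer, coefs = biodiversity_coefficients(),
                                 epsilon = 0.01) {
  ab <- project_relative_abundance(layer, coefs)
  sim <- project_compositional_similarity(layer, coefs, epsilon)
  structure(
    list(sr = project_relative_sr(layer, coefs),
         abundance = ab, similarity = sim, bii = compute_bii(ab, sim),
         grid = if (inherits(layer, "predicts_layer")) layer$grid else NULL,
         scenario = if (inherits(layer, "predicts_layer")) layer$scenario
                    else NULL),
    class = "biodiversity_maps"
  )
}

#' @export
print.biodiversity_maps <- function(x, ...) {
  cat(sprintf(
    "<biodiversity_maps>%s mean SR %.1f%%, abundance %.1f%%, BII %.1f%%\n",
    if (!is.null(x$scenario)) paste0(" [", x$scenario, "]") else "",
    mean(x$sr), mean(x$abundance), mean(x$bii)))
  invisible(x)
}

#' Simulate site-level biodiversity observations from class coefficients
#'
#' Generates synthetic survey sites for the coefficient-recovery helper:
#' species richness is Poisson with log mean `sr_intercept + sr_coef`,
#' square-root abundance and adjusted-logit similarity are Gaussian around
#' the class coefficient.
#'
#' @param coefs A [biodiversity_coefficients()] object (the truth).
#' @param n_per_class Sites per class.
#' @param sr_intercept Log-scale intercept for SR (default `log(40)`).
#' @param ab_sd,sim_sd Residual standard deviations.
#' @param seed RNG seed.
#' @return Data frame with columns `class`, `sr`, `sqrt_abundance`,
#'   `logit_similarity`.
#' @export
simulate_biodiversity_sites <- function(coefs, n_per_class = 200,
                                        sr_intercept = log(40),
                                        ab_sd = 0.05, sim_sd = 0.3,
                                        seed = 1L) {
  set.seed(seed)
  keys <- coefs$key
  cls <- rep(keys, each = n_per_class)
  sr_mu <- exp(sr_intercept + rep(coefs$sr_coef, each = n_per_class))
  data.frame(
    class = cls,
    sr = stats::rpois(length(cls), sr_mu),
    sqrt_abundance = stats::rnorm(
      length(cls), rep(coefs$abundance_coef, each = n_per_class), ab_sd),
    logit_similarity = stats::rnorm(
      length(cls), rep(coefs$similarity_coef, each = n_per_class), sim_sd),
    stringsAsFactors = FALSE
  )
}

#' Estimate class coefficients from site-level data (fixed effects only)
#'
#' Maximum-likelihood recovery of the class coefficients from simulated (or
#' real) site observations: a Poisson GLM with log link for species richness
#' (effects relative to the primary class), and per-class means for the
#' square-root abundance and adjusted-logit similarity scales. Random
#' effects are deliberately omitted.
#'
#' @param sites Data frame as returned by [simulate_biodiversity_sites()].
#' @param reference Reference class, default `"primary"`.
#' @return Data frame with columns `key`, `sr_coef` (relative to the
#'   reference), `abundance_coef`, `similarity_coef`.
#' @export
fit_biodiversity_coefficients <- function(sites, reference = "primary") {
  sites$class <- stats::relevel(factor(sites$class), ref = reference)
  fit_sr <- stats::glm(sr ~ class, family = stats::poisson(), data = sites)
  keys <- levels(sites$class)
  eff <- rep(0, length(keys)); names(eff) <- keys
  ce <- stats::coef(fit_sr)
  for (k in keys[-1]) eff[k] <- ce[[paste0("class", k)]]
  ab <- tapply(sites$sqrt_abundance, sites$class, mean)
  sim <- tapply(sites$logit_similarity, sites$class, mean)
  data.frame(key = keys, sr_coef = eff[keys],
             abundance_coef = as.numeric(ab[keys]),
             similarity_coef = as.numeric(sim[keys]),
             row.names = NULL, stringsAsFactors = FALSE)
}
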