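# Monotone land-use intensity share models. The original analysis estimated
# the share of each management-intensity class from yield (crops) or ruminant
# density (pasture) with generalized additive models; here the same monotone
# link is represented by an ordered-logistic share curve, whose cutpoints and
# slope are the tunable parameters.

#' Ordered-logistic crop intensity share model
#'
#' Shares of the minimal / light / intense management classes as a function
#' of yield: cumulative share of classes up to k is
#' `plogis(cutpoint_k - slope * yield)`. Minimal share is non-increasing and
#' intense share non-decreasing in yield; shares always sum to one.
#'
#' @param cutpoints Two increasing cutpoints on the yield scale (tDM/ha).
#' @param slope Positive slope (per tDM/ha).
#' @return An object of class `share_model`.
#' @export
intensity_share_model <- function(cutpoints = c(3.5, 6.5), slope = 1) {
  if (length(cutpoints) != 2 || diff(cutpoints) <= 0)
    stop("`cutpoints` must be two increasing values")
  if (slope <= 0) stop("`slope` must be positive")
  structure(list(cutpoints = cutpoints, slope = slope), class = "share_model")
}

#' Crop intensity shares at given yields
#'
#' @param yield Yield(s), tDM/ha, >= 0 (vector or matrix).
#' @param model An [intensity_share_model()].
#' @return A list of components `minimal`, `light`, `intense`, each with the
#'   shape of `yield`; the three sum to 1 elementwise.
#' @examples
#' intensity_shares(4.5, intensity_share_model(c(3, 6), 1))
#' @export
intensity_shares <- function(yield, model = intensity_share_model()) {
  if (any(!is.finite(yield)) || any(yield < 0))
    stop("`yield` must be finite and non-negative")
  cum1 <- stats::plogis(model$cutpoints[1] - model$slope * yield)
  cum2 <- stats::plogis(model$cutpoints[2] - model$slope * yield)
  list(minimal = cum1, light = cum2 - cum1, intense = 1 - cum2)
}

#' Ordered-logistic pasture intensity share model
#'
#' Shares of light vs intense pasture management as a function of a ruminant
#' stocking-rate proxy (heads/ha); the light share is
#' `plogis(cutpoint - slope * stocking)` and decreases with stocking.
#'
#' @param cutpoint Cutpoint on the stocking scale (heads/ha).
#' @param slope Positive slope (per heads/ha).
#' @export
pasture_share_model <- function(cutpoint = 1.2, slope = 1.5) {
  if (slope <= 0) stop("`slope` must be positive")
  structure(list(cutpoint = cutpoint, slope = slope),
            class = "pasture_share_model")
}

#' Pasture intensity shares at given stocking rates
#'
#' @param stocking Stocking proxy (heads/ha), >= 0.
#' @param model A [pasture_share_model()].
#' @return List with components `light` and `intense` summing to 1.
#' @export
pasture_shares <- function(stocking, model = pasture_share_model()) {
  if (any(!is.finite(stocking)) || any(stocking < 0))
    stop("`stocking` must be finite and non-negative")
  light <- stats::plogis(model$cutpoint - model$slope * stocking)
  list(light = light, intense = 1 - light)
}
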