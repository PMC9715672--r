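# Nitrogen-yield link: saturating (Michaelis-Menten) response.

#' Crop yield as a saturating function of nitrogen application
#'
#' Michaelis-Menten response, the classical concave production function used
#' to link fertilizer input to yield:
#' \deqn{y(n) = y_{min} + (y_{max} - y_{min}) \frac{n}{k_{half} + n}}
#' Strictly increasing and concave in `n_rate`; `y_min` is the zero-input
#' yield and `k_half` the application rate at which half of the attainable
#' yield gain is realized.
#'
#' @param n_rate Nitrogen application rate(s), kgN/ha; must be >= 0.
#' @param y_min,y_max Minimum and asymptotic yield, tDM/ha (`y_min < y_max`).
#' @param k_half Half-saturation constant, kgN/ha (> 0).
#' @return Yield in tDM/ha, same shape as `n_rate`.
#' @examples
#' nitrogen_yield_response(150, y_min = 2, y_max = 8, k_half = 100)  # 5.6
#' @export
nitrogen_yield_response <- function(n_rate, y_min = 2, y_max = 8,
                                    k_half = 100) {
  if (any(!is.finite(n_rate)) || any(n_rate < 0))
    stop("`n_rate` must be finite and non-negative")
  if (y_min >= y_max) stop("`y_min` must be smaller than `y_max`")
  if (k_half <= 0) stop("`k_half` must be positive")
  y_min + (y_max - y_min) * n_rate / (k_half + n_rate)
}
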