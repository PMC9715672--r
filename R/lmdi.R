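# Logarithmic mean Divisia index (LMDI) decomposition of indicator
# differences into an area effect and an intensity effect.

#' Logarithmic mean of two positive numbers
#'
#' `L(a, b) = (a - b) / (log(a) - log(b))` for `a != b`, and `a` when
#' `a == b`. Always lies between `min(a, b)` and `max(a, b)`. Vectorized.
#'
#' @param a,b Positive numbers.
#' @export
log_mean <- function(a, b) {
  if (any(a <= 0) || any(b <= 0))
    stop("`log_mean` requires strictly positive arguments")
  # (a - b)/log(a/b) evaluated as b*d/log1p(d) with d = (a-b)/b, which stays
  # accurate as a -> b where the naive log difference cancels catastrophically
  d <- (a - b) / b
  out <- ifelse(a == b, a, b * d / log1p(d))
  as.numeric(out)
}

#' LMDI breakdown of indicator differences into area and intensity effects
#'
#' For each land use with indicator levels `E_b`, `E_hN` (Baseline,
#' Halving-N) and areas `A_b`, `A_hN`, the difference `E_hN - E_b` is split
#' exactly into
#' \deqn{\Delta E^A = L(E_{hN}, E_b) \log(A_{hN}/A_b)}
#' \deqn{\Delta E^I = L(E_{hN}, E_b) \log(e_{hN}/e_b)}
#' with per-area intensities `e = E/A` and the logarithmic mean `L`. The
#' identity `E/A * A = E` makes the decomposition additive with no residual:
#' `dE_area + dE_intensity = E_hN - E_b` exactly.
#'
#' Levels or areas below `floor` are raised to the floor (with a warning)
#' before taking logs; the decomposition operates on positive levels, never
#' on differences. A land use with zero area in exactly one scenario gets
#' the whole difference as area effect (limit convention) and is flagged.
#' BII cannot be decomposed — it is a product of two indicators, not an
#' extensive level — and asking for it is an error.
#'
#' @param states Data frame with columns `land_use`, `E_b`, `E_hN`, `A_b`,
#'   `A_hN` (levels in indicator units, areas in Mha).
#' @param indicator Optional indicator name recorded in the output;
#'   `"bii"` raises an error.
#' @param floor Positive floor applied to levels and areas before logs.
#' @return Data frame of class `breakdown_result`: the input columns plus
#'   `dE`, `dE_area`, `dE_intensity` and logical `flagged`.
#' @export
lmdi_breakdown <- function(states, indicator = NULL, floor = 1e-9) {
  if (!is.null(indicator) && tolower(indicator) %in% c("bii", "bii_percent"))
    stop("the BII indicator cannot be decomposed: it is the product of ",
         "abundance and compositional similarity, not an extensive level")
  needed <- c("land_use", "E_b", "E_hN", "A_b", "A_hN")
  if (!all(needed %in% names(states)))
    stop("`states` must have columns ", paste(needed, collapse = ", "))
  if (floor <= 0) stop("`floor` must be positive")

  E_b <- states$E_b; E_hN <- states$E_hN
  A_b <- states$A_b; A_hN <- states$A_hN
  zero_one_side <- xor(A_b <= 0, A_hN <= 0)
  if (any(c(E_b, E_hN, A_b, A_hN) < floor)) {
    warning("levels or areas below the floor (", floor,
            ") were raised to it before taking logs")
    E_b <- pmax(E_b, floor); E_hN <- pmax(E_hN, floor)
    A_b <- pmax(A_b, floor); A_hN <- pmax(A_hN, floor)
  }

  L <- log_mean(E_hN, E_b)
  dE <- states$E_hN - states$E_b
  dE_area <- L * log(A_hN / A_b)
  dE_int <- L * log((E_hN / A_hN) / (E_b / A_b))
  # Limit convention: all-area when the land use exists in only one scenario.
  dE_area[zero_one_side] <- dE[zero_one_side]
  dE_int[zero_one_side] <- 0

  out <- data.frame(land_use = states$land_use,
                    E_b = states$E_b, E_hN = states$E_hN,
                    A_b = states$A_b, A_hN = states$A_hN,
                    dE = dE, dE_area = dE_area, dE_intensity = dE_int,
                    flagged = zero_one_side, stringsAsFactors = FALSE)
  if (!is.null(indicator)) attr(out, "indicator") <- indicator
  class(out) <- c("breakdown_result", "data.frame")
  out
}

#' @export
print.breakdown_result <- function(x, digits = 3, ...) {
  ind <- attr(x, "indicator")
  cat(sprintf("<breakdown_result>%s\n",
              if (!is.null(ind)) paste0(" ", ind) else ""))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
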