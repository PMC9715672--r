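# Win/Loss quadrant classification of joint carbon and biodiversity change.

QUADRANT_LEVELS <- c("I_win_win", "II_loss_win", "III_loss_loss",
                     "IV_win_loss", "no_change")

#' Classify grid cells into Win/Loss quadrants
#'
#' Each cell is placed by the joint sign of its carbon change (y axis) and
#' biodiversity change (x axis): quadrant I (Win-Win) has both positive,
#' II (Loss-Win) carbon loss with biodiversity gain, III (Loss-Loss) both
#' negative, IV (Win-Loss) carbon gain with biodiversity loss. Cells with
#' either change within `tolerance` of zero fall into a no-change residual.
#' Percentages use all grid points as the denominator and partition to 100.
#'
#' @param d_carbon,d_bio Matrices of per-cell changes on the same grid.
#' @param tolerance Non-negative half-width of the no-change band (default 0:
#'   only exact zeros are "no change").
#' @return Object of class `quadrant_summary`: data frame with columns
#'   `quadrant`, `n`, `percent`.
#' @export
classify_quadrants <- function(d_carbon, d_bio, tolerance = 0) {
  if (!identical(dim(d_carbon), dim(d_bio)))
    stop("change maps are not on the same grid")
  if (tolerance < 0) stop("`tolerance` must be non-negative")
  dc <- as.vector(d_carbon); db <- as.vector(d_bio)
  none <- abs(dc) <= tolerance | abs(db) <= tolerance
  q <- character(length(dc))
  q[none] <- "no_change"
  q[!none & dc > 0 & db > 0] <- "I_win_win"
  q[!none & dc < 0 & db > 0] <- "II_loss_win"
  q[!none & dc < 0 & db < 0] <- "III_loss_loss"
  q[!none & dc > 0 & db < 0] <- "IV_win_loss"
  n <- vapply(QUADRANT_LEVELS, function(l) sum(q == l), numeric(1))
  out <- data.frame(quadrant = QUADRANT_LEVELS, n = as.integer(n),
                    percent = 100 * n / length(dc),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("quadrant_summary", "data.frame")
  out
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat("<quadrant_summary>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy report of quadrant summaries across indicator pairs and scenarios
#'
#' @param summaries Named list of `quadrant_summary` objects; names are used
#'   as the indicator-pair label (e.g. `"soil_c_vs_sr"`).
#' @param family Scenario family label attached to every row.
#' @return Data frame with columns `family`, `pair`, `quadrant`, `n`,
#'   `percent`; zero rows when `summaries` is empty.
#' @export
quadrant_report <- function(summaries, family = NA_character_) {
  if (length(summaries) == 0)
    return(data.frame(family = character(), pair = character(),
                      quadrant = character(), n = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(family = family, pair = nm, quadrant = s$quadrant,
               n = s$n, percent = s$percent, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Modal quadrant of a summary (excluding the no-change residual or not)
#'
#' @param summary A `quadrant_summary`.
#' @param include_no_change Whether the no-change residual may be modal.
#' @return The quadrant label with the highest percentage.
#' @export
modal_quadrant <- function(summary, include_no_change = FALSE) {
  s <- summary
  if (!include_no_change) s <- s[s$quadrant != "no_change", , drop = FALSE]
  s$quadrant[which.max(s$percent)]
}
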