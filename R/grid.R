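#' The descending probability-of-loss grid
#'
#' Gamble ladders present a fixed sequence of loss probabilities, starting at
#' 1-in-2 and descending to 1-in-a-million. Probabilities are carried around
#' as exact fraction strings (`"1/2"`, ..., `"1/1000000"`) in files to avoid
#' floating-point drift, and parsed to numeric for computation.
#'
#' @return Named numeric vector of the eight grid probabilities in descending
#'   order; names are the exact fraction labels.
#' @examples
#' probability_grid()
#' @export
probability_grid <- function() {
  stats::setNames(.sg_grid_values, .sg_grid_labels)
}

.sg_grid_labels <- c("1/2", "1/5", "1/10", "1/100", "1/1000",
                     "1/10000", "1/100000", "1/1000000")
.sg_grid_values <- c(1 / 2, 1 / 5, 1 / 10, 1 / 100, 1e-3, 1e-4, 1e-5, 1e-6)

#' Parse grid probability labels
#'
#' @param label Character vector of fraction labels from the grid.
#' @return Numeric probabilities.
#' @export
parse_probability <- function(label) {
  idx <- match(label, .sg_grid_labels)
  if (anyNA(idx)) {
    stop("non-grid probability label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  .sg_grid_values[idx]
}

#' Format grid probabilities as exact labels
#'
#' @param p Numeric probabilities that must match the grid exactly.
#' @return Character labels.
#' @export
format_probability <- function(p) {
  idx <- vapply(p, function(x) {
    j <- which(abs(.sg_grid_values - x) < 1e-12)
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx)) stop("probability not on the grid", call. = FALSE)
  .sg_grid_labels[idx]
}

#' Ordinal well-being states
#'
#' Six states in fixed ascending order of well-being: `F` (death), then the
#' living states `E`, `D`, `C`, `B`, `A` described by the survey vignettes
#' (`A` the best). The rank is a total order and `F` is the unique non-living
#' state.
#'
#' @return Character vector of state labels in ascending rank order.
#' @export
state_levels <- function() .sg_states

.sg_states <- c("F", "E", "D", "C", "B", "A")

#' State rank (1 = death, 6 = best living state)
#' @param state Character vector of state labels.
#' @return Integer ranks.
#' @export
state_rank <- function(state) {
  r <- match(state, .sg_states)
  if (anyNA(r)) {
    stop("unknown state label(s): ",
         paste(unique(state[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r
}

is_living <- function(state) state != "F"
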