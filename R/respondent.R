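#' Construct a survey respondent record
#'
#' A respondent carries the survey condition, demographics, party, the
#' five-item political-attitude scale (summed, leftwards-positive), the five
#' vignette life-satisfaction ratings (integers 0-10 for states A-E), and the
#' twelve choice ladders: four adjacent personal, four adjacent societal and
#' four non-adjacent personal gambles. The `order_violation` flag is derived:
#' it is set exactly when the ratings are not monotone A >= B >= C >= D >= E.
#'
#' @param id Participant identifier (scalar).
#' @param condition `"gambles_first"` or `"ls_first"`.
#' @param age_band,sex,party Character scalars (free-form demographic codes).
#' @param political_items Integer vector of length 5.
#' @param vignette_ratings Named numeric vector with names A-E, values 0-10.
#' @param ladders List of 12 `sg_ladder` objects.
#' @param attention_fail Logical; failed an attention check.
#' @return Object of class `sg_respondent`.
#' @export
respondent <- function(id, condition = c("gambles_first", "ls_first"),
                       age_band = "25-34", sex = "female", party = "none",
                       political_items = rep(3L, 5L),
                       vignette_ratings = c(A = 10, B = 8, C = 6, D = 4, E = 2),
                       ladders = list(), attention_fail = FALSE) {
  condition <- match.arg(condition)
  if (length(political_items) != 5L || anyNA(political_items)) {
    stop("political_items must be 5 non-missing values", call. = FALSE)
  }
  need <- c("A", "B", "C", "D", "E")
  if (!all(need %in% names(vignette_ratings))) {
    stop("vignette_ratings must be named A-E", call. = FALSE)
  }
  vr <- vignette_ratings[need]
  if (any(vr < 0 | vr > 10 | vr != round(vr))) {
    stop("vignette ratings must be integers in 0-10", call. = FALSE)
  }
  blocks <- vapply(ladders, function(l) l$gamble$block, character(1))
  counts <- table(factor(blocks, levels = c("adjacent_personal",
                                            "adjacent_societal",
                                            "nonadjacent_personal")))
  if (length(ladders) != 12L || any(counts != 4L)) {
    stop("respondent needs 12 ladders: 4 adjacent personal, 4 adjacent ",
         "societal, 4 nonadjacent personal", call. = FALSE)
  }
  for (blk in c("adjacent_personal", "adjacent_societal")) {
    bl <- sort(vapply(ladders[blocks == blk],
                      function(l) l$gamble$baseline, character(1)))
    if (!identical(bl, sort(c("E", "D", "C", "B")))) {
      stop("adjacent block must chain baselines E, D, C, B", call. = FALSE)
    }
  }
  structure(list(id = id, condition = condition, age_band = age_band,
                 sex = sex, party = party,
                 political_items = as.integer(political_items),
                 political_score = sum(as.integer(political_items)),
                 vignette_ratings = vr,
                 ladders = ladders,
                 flags = list(order_violation = is.unsorted(rev(vr)),
                              attention_fail = isTRUE(attention_fail))),
            class = "sg_respondent")
}

#' @export
print.sg_respondent <- function(x, ...) {
  cat(sprintf("<respondent %s> %s, party=%s, politics=%d%s\n",
              as.character(x$id), x$condition, x$party, x$political_score,
              if (x$flags$order_violation) ", order violation" else ""))
  invisible(x)
}

#' Binned life-satisfaction distribution
#'
#' Population shares over the four life-satisfaction ranges used in the
#' seasonally adjusted national releases: 0-4, 5-6, 7-8 and 9-10. Each bin is
#' assigned a representative within-bin life-satisfaction value (default: the
#' bin midpoints 2, 5.5, 7.5, 9.5) at which utility functions are evaluated.
#'
#' @param shares Numeric vector of 4 non-negative shares summing to 1.
#' @param representative_ls Numeric vector of 4 within-bin representative
#'   values.
#' @param normalise If `TRUE`, shares are rescaled to sum to one; otherwise a
#'   deviation of more than 1e-9 from 1 is an error.
#' @return Object of class `ls_distribution` with elements `ranges`, `shares`
#'   and `representative_ls`.
#' @examples
#' binned_ls_distribution(c(0.06, 0.10, 0.50, 0.34))
#' @export
binned_ls_distribution <- function(shares,
                                   representative_ls = c(2, 5.5, 7.5, 9.5),
                                   normalise = FALSE) {
  if (length(shares) != 4L || any(shares < 0)) {
    stop("shares must be 4 non-negative values for bins 0-4, 5-6, 7-8, 9-10",
         call. = FALSE)
  }
  if (normalise) {
    if (sum(shares) <= 0) stop("shares sum to zero", call. = FALSE)
    shares <- shares / sum(shares)
  } else if (abs(sum(shares) - 1) > 1e-9) {
    stop("shares must sum to 1 (|sum - 1| <= 1e-9) unless normalise = TRUE",
         call. = FALSE)
  }
  if (length(representative_ls) != 4L) {
    stop("representative_ls must have 4 values", call. = FALSE)
  }
  structure(list(ranges = c("0-4", "5-6", "7-8", "9-10"),
                 shares = as.numeric(shares),
                 representative_ls = as.numeric(representative_ls)),
            class = "ls_distribution")
}

#' Mean life satisfaction of a binned distribution
#'
#' Share-weighted mean of the bins' representative values.
#'
#' @param dist An `ls_distribution`.
#' @return Numeric scalar.
#' @export
distribution_mean <- function(dist) {
  stopifnot(inherits(dist, "ls_distribution"))
  sum(dist$shares * dist$representative_ls)
}

#' @export
print.ls_distribution <- function(x, ...) {
  cat("<ls distribution>\n")
  for (i in seq_along(x$ranges)) {
    cat(sprintf("  %-5s share %.4f (rep ls %.1f)\n",
                x$ranges[i], x$shares[i], x$representative_ls[i]))
  }
  invisible(x)
}
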