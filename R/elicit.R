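#' Chained utilities from four adjacent-gamble indifference points
#'
#' Each standard gamble at indifference satisfies
#' `U_b = p * U_l + (1 - p) * U_w`. With states in ascending order
#' F (death), E, D, C, B, A and the chain of adjacent gambles
#' E vs. D/F, D vs. C/E, C vs. B/D, B vs. A/C, fixing the estimation anchors
#' `U_F = 0, U_E = 1` lets the equations be solved sequentially upward:
#' `U_w = (U_b - p * U_l) / (1 - p)`. An indifference point of `p = 0`
#' (infinite aversion) yields an exactly flat step `U_w = U_b`.
#'
#' The estimation anchoring (`U_F = 0, U_E = 1`) keeps the solve
#' well-conditioned; use [rescale_to_reporting()] for the reporting anchoring
#' `U_F = 0, U_A = 1`.
#'
#' @param points List of four `sg_indiff` objects for baselines E, D, C, B in
#'   that order; none may be undecidable and none may have `p = 1`.
#' @return Object of class `sg_curve`: list with `utilities` (named numeric
#'   over F, E, D, C, B, A), `anchoring = "estimation"`.
#' @examples
#' pts <- replicate(4, structure(list(p = 0.5, status = "interior"),
#'                               class = "sg_indiff"), simplify = FALSE)
#' chained_utilities(pts)$utilities  # 0, 1, 2, 3, 4, 5
#' @export
chained_utilities <- function(points) {
  if (length(points) != 4L) stop("need four indifference points", call. = FALSE)
  p <- vapply(points, function(x) x$p, numeric(1))
  if (anyNA(p)) {
    stop("curve not estimable: undecidable gamble in the chain", call. = FALSE)
  }
  if (any(p >= 1)) stop("invalid indifference probability p >= 1", call. = FALSE)
  if (any(p < 0)) stop("invalid indifference probability p < 0", call. = FALSE)
  u <- c(F = 0, E = 1, D = NA_real_, C = NA_real_, B = NA_real_, A = NA_real_)
  for (k in 1:4) {
    # baseline state k+1, lose state k, win state k+2 (ascending-rank indexing)
    u[k + 2L] <- (u[k + 1L] - p[k] * u[k]) / (1 - p[k])
  }
  structure(list(utilities = u, anchoring = "estimation"), class = "sg_curve")
}

#' @export
print.sg_curve <- function(x, ...) {
  cat(sprintf("<utility curve, %s anchoring>\n", x$anchoring))
  print(round(x$utilities, 4))
  invisible(x)
}

#' Rescale a utility curve to the reporting anchoring
#'
#' Reporting fixes `U_F = 0, U_A = 1`: all utilities are divided by the
#' estimation-scale `U_A`. Idempotent on curves already in reporting scale.
#'
#' @param curve An `sg_curve`.
#' @return An `sg_curve` with `anchoring = "reporting"`.
#' @export
rescale_to_reporting <- function(curve) {
  stopifnot(inherits(curve, "sg_curve"))
  ua <- curve$utilities[["A"]]
  if (ua <= 0) {
    stop("degenerate all-flat curve (U_A = 0): cannot rescale", call. = FALSE)
  }
  structure(list(utilities = curve$utilities / ua, anchoring = "reporting"),
            class = "sg_curve")
}

#' Living-states utility curve (no-death chain)
#'
#' Re-estimates the curve excluding the gamble with risk of death, using only
#' the three chained equations over living states with anchors
#' `U_E = 0, U_A = 1`:
#' `U_D = p2*U_E + (1-p2)*U_C`, `U_C = p3*U_D + (1-p3)*U_B`,
#' `U_B = p4*U_C + (1-p4)*U_A`. The system is coupled rather than sequential
#' and is solved in closed form by substitution. Needed because some
#' respondents show infinite aversion to death gambles, which flattens the
#' living portion of the full chain to a single point.
#'
#' @param points List of three `sg_indiff` for baselines D, C, B (the
#'   chain without the death gamble), none undecidable.
#' @return `sg_curve` over E, D, C, B, A with `anchoring = "living"`.
#' @export
living_utilities <- function(points) {
  if (length(points) != 3L) stop("need three indifference points", call. = FALSE)
  p <- vapply(points, function(x) x$p, numeric(1))
  if (anyNA(p)) {
    stop("curve not estimable: undecidable gamble in the chain", call. = FALSE)
  }
  if (any(p < 0 | p >= 1)) stop("invalid indifference probability", call. = FALSE)
  p2 <- p[1]; p3 <- p[2]; p4 <- p[3]
  denom <- 1 - p3 * (1 - p2) - (1 - p3) * p4
  uc <- (1 - p3) * (1 - p4) / denom
  ud <- (1 - p2) * uc
  ub <- p4 * uc + (1 - p4)
  structure(list(utilities = c(E = 0, D = ud, C = uc, B = ub, A = 1),
                 anchoring = "living"),
            class = "sg_curve")
}

#' Elicit indifference points, lambdas and curves for a cohort
#'
#' Runs the full elicitation stage: per (participant, gamble) indifference
#' probabilities (optionally CPT-reweighted, see [weighted_reanalysis()]),
#' the loss-aversion records, and per-participant chained utility curves in
#' estimation, reporting and living (no-death) anchorings for both contexts.
#'
#' @param respondents List of `sg_respondent`.
#' @param weighting Optional `cpt_params`; when supplied, every indifference
#'   probability `p` is replaced by the CPT effective probability `p*` before
#'   utilities and lambdas are computed (`mode = "indifference"`), or each
#'   accepted/rejected grid endpoint is reweighted before the log-midpoint is
#'   taken (`mode = "endpoint"`).
#' @param mode Weighting mode, ignored when `weighting` is `NULL`.
#' @return List with `points` (data.frame: id, gamble_index, context, block,
#'   label, baseline, p, status, lambda, lambda_prime) and `curves` (list per
#'   participant id with `personal`/`societal` estimation, reporting and
#'   living `sg_curve`s, `NULL` where not estimable).
#' @export
elicit_cohort <- function(respondents, weighting = NULL,
                          mode = c("indifference", "endpoint")) {
  mode <- match.arg(mode)
  pts <- lapply(respondents, function(r) {
    rows <- lapply(seq_along(r$ladders), function(gi) {
      l <- r$ladders[[gi]]
      ip <- if (is.null(weighting) || mode == "indifference") {
        indifference_probability(l)
      } else {
        .endpoint_weighted_indifference(l, weighting)
      }
      if (!is.null(weighting) && mode == "indifference" && !is.na(ip$p)) {
        ip$p <- effective_probability(ip$p, weighting)
      }
      lam <- if (is.na(ip$p)) NA_real_ else lambda_from_p(ip$p)
      data.frame(id = as.character(r$id), gamble_index = gi,
                 context = l$gamble$context, block = l$gamble$block,
                 label = gamble_label(l$gamble), baseline = l$gamble$baseline,
                 p = ip$p, status = ip$status, lambda = lam,
                 lambda_prime = if (is.na(lam)) NA_real_ else lambda_prime(lam),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  points <- do.call(rbind, pts)
  curves <- lapply(respondents, function(r) {
    id <- as.character(r$id)
    sub <- points[points$id == id, , drop = FALSE]
    out <- list()
    for (ctx in c("personal", "societal")) {
      blk <- if (ctx == "personal") "adjacent_personal" else "adjacent_societal"
      adj <- sub[sub$block == blk, , drop = FALSE]
      adj <- adj[match(c("E", "D", "C", "B"), adj$baseline), , drop = FALSE]
      mk <- function(pp) structure(list(p = pp, status = "interior"),
                                   class = "sg_indiff")
      est <- rep_ <- liv <- NULL
      if (!anyNA(adj$p)) {
        est <- chained_utilities(lapply(adj$p, mk))
        if (est$utilities[["A"]] > 0) rep_ <- rescale_to_reporting(est)
      }
      if (!anyNA(adj$p[2:4])) {
        liv <- living_utilities(lapply(adj$p[2:4], mk))
      }
      out[[ctx]] <- list(estimation = est, reporting = rep_, living = liv)
    }
    out
  })
  names(curves) <- vapply(respondents, function(r) as.character(r$id),
                          character(1))
  list(points = points, curves = curves)
}

# Endpoint-wise CPT weighting: transform the bracketing grid probabilities
# before taking the log midpoint.
.endpoint_weighted_indifference <- function(ladder, params) {
  ip <- indifference_probability(ladder)
  if (is.na(ip$p)) return(ip)
  acc <- ladder$p[ladder$decisions == "accept"]
  rej <- ladder$p[ladder$decisions == "reject"]
  p_acc <- if (length(acc)) effective_probability(max(acc), params) else 0
  p_rej <- if (length(rej)) effective_probability(min(rej), params) else 1
  ip$p <- sqrt(p_acc * p_rej)
  ip
}
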