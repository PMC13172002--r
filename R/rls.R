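#' Piecewise-linear utility function over the life-satisfaction scale
#'
#' Monotone nondecreasing piecewise-linear function through knots
#' `(ls, utility)`. Below the lowest knot it extrapolates linearly with the
#' lowest segment's slope (clamped nonnegative); above the highest knot it is
#' constant. Evaluable on `[0, 10]`; invertible on its strictly increasing
#' range, returning the lowest life-satisfaction value attaining a utility.
#'
#' @param ls Strictly increasing knot positions on the 0-10 scale.
#' @param utility Nondecreasing utilities at the knots.
#' @return Object of class `ls_function`.
#' @export
ls_utility_function <- function(ls, utility) {
  if (length(ls) != length(utility) || length(ls) < 2L) {
    stop("need at least two knots", call. = FALSE)
  }
  if (any(diff(ls) <= 0)) stop("knot positions must be strictly increasing",
                               call. = FALSE)
  if (any(diff(utility) < -1e-12)) {
    stop("knot utilities must be nondecreasing", call. = FALSE)
  }
  structure(list(ls = as.numeric(ls), utility = as.numeric(utility)),
            class = "ls_function")
}

#' @export
print.ls_function <- function(x, ...) {
  cat("<ls utility function>\n")
  print(stats::setNames(round(x$utility, 4), format(x$ls, digits = 3)))
  invisible(x)
}

#' Evaluate an `ls_function`
#' @param fn An `ls_function`.
#' @param x Life-satisfaction values; vectorised.
#' @return Utilities.
#' @export
evaluate_ls <- function(fn, x) {
  stopifnot(inherits(fn, "ls_function"))
  k <- length(fn$ls)
  slope0 <- max(0, (fn$utility[2] - fn$utility[1]) / (fn$ls[2] - fn$ls[1]))
  out <- stats::approx(fn$ls, fn$utility, xout = pmin(x, fn$ls[k]),
                       rule = 2)$y
  low <- x < fn$ls[1]
  out[low] <- fn$utility[1] + slope0 * (x[low] - fn$ls[1])
  out
}

#' Map a living-states utility curve onto the life-satisfaction scale
#'
#' Places the five living-state utilities at x positions given by the
#' cohort's mean vignette life-satisfaction ratings for states E-A, yielding
#' a monotone piecewise-linear utility-of-life-satisfaction function.
#'
#' @param curve An `sg_curve` over the living states (e.g. from
#'   [living_utilities()]); any anchoring containing E..A works.
#' @param x_positions Named numeric (E, D, C, B, A): scale positions.
#' @return An `ls_function`.
#' @export
curve_to_ls_function <- function(curve,
                                 x_positions = c(E = 2, D = 4, C = 6,
                                                 B = 8, A = 10)) {
  stopifnot(inherits(curve, "sg_curve"))
  st <- c("E", "D", "C", "B", "A")
  u <- curve$utilities[st]
  if (anyNA(u)) stop("curve must cover states E..A", call. = FALSE)
  x <- x_positions[st]
  if (anyNA(x)) stop("x_positions must be named E..A", call. = FALSE)
  ls_utility_function(x, u)
}

#' Mean vignette-rating positions for states E-A
#'
#' @param respondents A cohort; order-violating respondents are excluded by
#'   default, mirroring the response filtering.
#' @param drop_violations Exclude respondents flagged `order_violation`.
#' @return Named numeric (E, D, C, B, A) of mean ratings.
#' @export
mean_vignette_positions <- function(respondents, drop_violations = TRUE) {
  keep <- respondents
  if (drop_violations) {
    keep <- Filter(function(r) !r$flags$order_violation, respondents)
  }
  if (!length(keep)) stop("no respondents", call. = FALSE)
  m <- rowMeans(vapply(keep, function(r) r$vignette_ratings[c("E", "D", "C",
                                                              "B", "A")],
                       numeric(5)))
  stats::setNames(m, c("E", "D", "C", "B", "A"))
}

#' Weighted SD of a function under a binned distribution
#' @keywords internal
.fn_sd <- function(fn, ref) {
  u <- evaluate_ls(fn, ref$representative_ls)
  mu <- sum(ref$shares * u)
  sqrt(sum(ref$shares * (u - mu)^2))
}

#' Normalise a utility function by a reference distribution
#'
#' Divides utilities by the share-weighted (population) standard deviation of
#' the function evaluated at the reference distribution's representative
#' life-satisfaction values. The normalised function has SD exactly 1 under
#' the reference, giving each individual curve equal "voting" power in
#' mean-utility aggregation. Flat functions (zero SD) cannot be normalised.
#'
#' @param fn An `ls_function`.
#' @param ref An `ls_distribution`.
#' @return A normalised `ls_function`.
#' @export
normalize_by_reference <- function(fn, ref) {
  stopifnot(inherits(fn, "ls_function"), inherits(ref, "ls_distribution"))
  s <- .fn_sd(fn, ref)
  if (s <= 0) {
    stop("flat utility function: zero SD under the reference distribution",
         call. = FALSE)
  }
  ls_utility_function(fn$ls, fn$utility / s)
}

#' Expected utility of a binned distribution
#'
#' `sum(share * fn(representative_ls))`; linear in the shares.
#'
#' @param fn An `ls_function`.
#' @param dist An `ls_distribution`.
#' @return Numeric scalar.
#' @export
expected_utility <- function(fn, dist) {
  stopifnot(inherits(fn, "ls_function"), inherits(dist, "ls_distribution"))
  sum(dist$shares * evaluate_ls(fn, dist$representative_ls))
}

#' Certainty-equivalent life satisfaction for a utility level
#'
#' Monotone inversion by bisection (to 1e-9 on the life-satisfaction scale):
#' the lowest ls in `[0, 10]` with `fn(ls) = u`. Utilities outside the
#' function's range on `[0, 10]` are clamped to the nearest endpoint, with a
#' `clamped` attribute set.
#'
#' @param fn An `ls_function`.
#' @param u Target utility.
#' @return Life-satisfaction value (attribute `clamped` = TRUE if out of
#'   range).
#' @export
certainty_equivalent <- function(fn, u) {
  lo <- 0; hi <- 10
  flo <- evaluate_ls(fn, lo); fhi <- evaluate_ls(fn, hi)
  if (u <= flo || u >= fhi) {
    if (u < flo - 1e-12 || u > fhi + 1e-12) {
      out <- if (u < flo) lo else hi
      attr(out, "clamped") <- TRUE
      return(out)
    }
    # at an endpoint value: still bisect to find the lowest attaining ls
  }
  # lowest ls attaining u: bisect on fn(x) >= u boundary
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (evaluate_ls(fn, mid) >= u) hi <- mid else lo <- mid
    if (hi - lo < 1e-9) break
  }
  hi
}

#' Representative Life Satisfaction of a binned distribution
#'
#' The constant life-satisfaction level equivalent, under a cohort's elicited
#' utility functions, to the observed distribution - an
#' equally-distributed-equivalent statistic with empirically measured
#' curvature. Three aggregation methods:
#'
#' * `"mean_utility"`: after normalising every function by the reference
#'   distribution (equal voting power), solves
#'   `sum_i fn_i(c) = sum_i E_dist[fn_i]` for `c` by bisection - the level
#'   giving the same total utility as the distribution. Flat (zero-SD)
#'   functions are excluded.
#' * `"median_participant"`: the median over participants of each
#'   participant's own certainty equivalent `CE(fn_i, E_dist[fn_i])` -
#'   normalisation-free and invariant to any strictly increasing transform of
#'   individual utilities; delivers the lowest level that 50% of participants
#'   would consider better than the distribution.
#' * `"median_curve"`: pointwise median of the normalised curves, then its
#'   certainty equivalent.
#'
#' @param functions List of `ls_function`, one per participant.
#' @param dist An `ls_distribution` to be summarised.
#' @param method Aggregation method.
#' @param ref Reference `ls_distribution` for SD normalisation; defaults to
#'   `dist` itself. Supplying a fixed reference keeps curves comparable when
#'   summarising alternative (possibly degenerate) distributions.
#' @return List: `rls`, `mean_ls` (distribution mean from the same bin
#'   representatives), `difference` (= rls - mean_ls), `method`, `n` (number
#'   of functions used).
#' @export
rls <- function(functions, dist,
                method = c("median_participant", "mean_utility",
                           "median_curve"), ref = dist) {
  method <- match.arg(method)
  functions <- Filter(Negate(is.null), functions)
  if (!length(functions)) stop("empty cohort", call. = FALSE)
  mean_ls <- distribution_mean(dist)

  if (method == "median_participant") {
    ces <- vapply(functions, function(fn) {
      as.numeric(certainty_equivalent(fn, expected_utility(fn, dist)))
    }, numeric(1))
    val <- stats::median(ces)
    n <- length(ces)
  } else {
    usable <- Filter(function(fn) .fn_sd(fn, ref) > 0, functions)
    if (!length(usable)) stop("no non-flat utility functions", call. = FALSE)
    norm <- lapply(usable, normalize_by_reference, ref = ref)
    n <- length(norm)
    if (method == "mean_utility") {
      target <- mean(vapply(norm, expected_utility, numeric(1), dist = dist))
      g <- function(c) mean(vapply(norm, evaluate_ls, numeric(1), x = c))
      lo <- 0; hi <- 10
      if (target <= g(lo)) {
        val <- lo
      } else if (target >= g(hi)) {
        val <- hi
      } else {
        for (it in 1:60) {
          mid <- (lo + hi) / 2
          if (g(mid) < target) lo <- mid else hi <- mid
          if (hi - lo < 1e-9) break
        }
        val <- (lo + hi) / 2
      }
    } else {  # median_curve
      grid <- seq(0, 10, by = 0.01)
      med <- apply(vapply(norm, evaluate_ls, numeric(length(grid)),
                          x = grid), 1L, stats::median)
      med_fn <- ls_utility_function(grid, cummax(med))
      val <- as.numeric(certainty_equivalent(med_fn,
                                             expected_utility(med_fn, dist)))
    }
  }
  list(rls = val, mean_ls = mean_ls, difference = val - mean_ls,
       method = method, n = n)
}

#' RLS summary table over contexts and methods
#'
#' Builds, for each context (personal, societal), the cohort's living-state
#' utility functions (no-death chained curves placed at the mean vignette
#' positions) and computes RLS by the mean-utility and median-participant
#' methods - the four headline cells.
#'
#' @param elicited Result of [elicit_cohort()].
#' @param respondents The cohort (for vignette positions).
#' @param dist An `ls_distribution`.
#' @param methods Methods to tabulate.
#' @return Data frame: `context`, `method`, `rls`, `mean_ls`, `difference`,
#'   `n`.
#' @export
rls_table <- function(elicited, respondents, dist,
                      methods = c("mean_utility", "median_participant")) {
  xpos <- mean_vignette_positions(respondents)
  rows <- list()
  for (ctx in c("personal", "societal")) {
    fns <- lapply(elicited$curves, function(cc) {
      liv <- cc[[ctx]]$living
      if (is.null(liv)) NULL else curve_to_ls_function(liv, xpos)
    })
    for (m in methods) {
      r <- rls(fns, dist, method = m)
      rows[[length(rows) + 1L]] <-
        data.frame(context = ctx, method = m, rls = r$rls,
                   mean_ls = r$mean_ls, difference = r$difference, n = r$n,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
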