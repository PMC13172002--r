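#' Cronbach's alpha
#'
#' Internal-consistency reliability `k/(k-1) * (1 - sum(item variances) /
#' variance(total score))`. Sample variances are used throughout; the ratio
#' is identical under the population-variance convention since the `n/(n-1)`
#' factor cancels. With `standardise = TRUE` items are scaled to unit
#' variance first, making the statistic invariant to item rescaling by
#' positive constants.
#'
#' @param items n x k numeric matrix (k >= 2, no missing values).
#' @param standardise Scale items to unit variance first.
#' @return Alpha (numeric scalar).
#' @export
cronbach_alpha <- function(items, standardise = FALSE) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("need at least 2 items", call. = FALSE)
  if (anyNA(items)) stop("missing values not supported", call. = FALSE)
  if (standardise) items <- scale(items, center = FALSE,
                                  scale = apply(items, 2, stats::sd))
  k <- ncol(items)
  total_var <- stats::var(rowSums(items))
  if (total_var <= 0) stop("zero total-score variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. `U` is oriented to the first sample: the number
#' of (x, y) pairs with x > y (plus half the ties), i.e. `U = 0` when every x
#' is below every y. Exact enumeration is used when the smaller group has at
#' most 8 observations and there are no ties; otherwise the tie-corrected
#' normal approximation (with continuity correction).
#'
#' @param x,y Numeric vectors (nonempty).
#' @return List with `U` and two-sided `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty",
                                     call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation; two-sided p from the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need paired vectors with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Minimum detectable correlation
#'
#' The smallest `|r|` whose two-sided p-value reaches `alpha` at sample size
#' `n`: inverting the t test, `r = t / sqrt(n - 2 + t^2)` with `t` the
#' two-sided critical value. This is the critical-value (50%-power) reading
#' of "would in principle be significant"; an 80%-power variant is available
#' and reports the correspondingly larger effect.
#'
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level.
#' @param power `0.5` (critical value, default) or any power in (0, 1), in
#'   which case the normal-approximation power calculation on the Fisher-z
#'   scale is inverted.
#' @return Minimum detectable `|r|`.
#' @export
mde_correlation <- function(n, alpha = 0.05, power = 0.5) {
  if (n < 4) stop("need n >= 4", call. = FALSE)
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  r_crit <- tcrit / sqrt(n - 2 + tcrit^2)
  if (abs(power - 0.5) < 1e-12) return(r_crit)
  # Fisher-z: detectable z-shift = (z_{1-a/2} + z_{power}) / sqrt(n - 3)
  zshift <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3)
  tanh(zshift)
}

#' Minimum detectable shift in median lambda'
#'
#' Smallest location shift between two groups of `lambda'` values that the
#' two-sided Mann-Whitney test detects at level `alpha` with the given power,
#' found by bisection over simulated normal samples at the stated dispersion.
#' Stochastic; controlled by `seed`.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param sd Dispersion of `lambda'` (e.g. 0.34 personal, 0.37 societal).
#' @param alpha Significance level.
#' @param power Target rejection rate (default 0.5, the critical-value
#'   convention).
#' @param n_sims Simulations per candidate shift.
#' @param seed RNG seed.
#' @return Minimum detectable shift in median `lambda'`.
#' @export
mde_median_lambda <- function(n1, n2, sd = 0.34, alpha = 0.05, power = 0.5,
                              n_sims = 400, seed = 1) {
  if (min(n1, n2) < 2) stop("group sizes must be >= 2", call. = FALSE)
  rejection_rate <- function(shift) {
    mean(vapply(seq_len(n_sims), function(s) {
      x <- stats::rnorm(n1, 0, sd)
      y <- stats::rnorm(n2, shift, sd)
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    }, numeric(1)) <= alpha)
  }
  set.seed(seed)
  lo <- 0; hi <- 4 * sd
  while (rejection_rate(hi) < power && hi < 32 * sd) hi <- hi * 2
  for (it in 1:12) {
    mid <- (lo + hi) / 2
    if (rejection_rate(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Cohort response-validation report
#'
#' Summarises the validation checks: sample size, order-violation and
#' attention-failure rates, per-context gamble completion (a participant
#' "completes" a context when none of its adjacent gambles is undecidable,
#' with a no-death variant ignoring the death gamble), vignette rating
#' medians, Cronbach's alpha for the political scale, and a Mann-Whitney
#' comparison of pooled personal aversion between the two survey conditions.
#'
#' @param respondents List of `sg_respondent`.
#' @param elicited Optional result of [elicit_cohort()] (computed if absent).
#' @return List of validation statistics.
#' @export
validate_cohort <- function(respondents, elicited = NULL) {
  if (is.null(elicited)) elicited <- elicit_cohort(respondents)
  pts <- elicited$points
  n <- length(respondents)
  ids <- vapply(respondents, function(r) as.character(r$id), character(1))

  complete <- function(ctx, baselines) {
    blk <- if (ctx == "personal") "adjacent_personal" else "adjacent_societal"
    sub <- pts[pts$block == blk & pts$baseline %in% baselines, , drop = FALSE]
    ok <- tapply(sub$status, sub$id, function(s) !any(s == "undecidable"))
    mean(ok[ids])
  }
  ratings <- vapply(respondents, function(r) r$vignette_ratings,
                    numeric(5))
  items <- t(vapply(respondents, function(r) as.numeric(r$political_items),
                    numeric(5)))
  cond <- vapply(respondents, function(r) r$condition, character(1))
  mlp <- participant_mean_lambda_prime(pts, "personal", "all")
  cond_cmp <- NULL
  if (nrow(mlp) >= 4L) {
    byc <- split(mlp$mean_lambda_prime, cond[match(mlp$id, ids)])
    if (length(byc) == 2L && all(lengths(byc) >= 2L)) {
      cond_cmp <- mann_whitney(byc[[1]], byc[[2]])
    }
  }
  list(n = n,
       order_violation_rate = mean(vapply(respondents, function(r)
         r$flags$order_violation, logical(1))),
       attention_fail_rate = mean(vapply(respondents, function(r)
         r$flags$attention_fail, logical(1))),
       completion_personal = complete("personal", c("E", "D", "C", "B")),
       completion_societal = complete("societal", c("E", "D", "C", "B")),
       completion_personal_no_death = complete("personal", c("D", "C", "B")),
       completion_societal_no_death = complete("societal", c("D", "C", "B")),
       vignette_medians = apply(ratings, 1, stats::median),
       cronbach_alpha_politics = cronbach_alpha(items),
       condition_comparison = cond_cmp)
}
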