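#' Loss aversion from an indifference probability
#'
#' At indifference the standard-gamble relation `U_b = p*U_l + (1-p)*U_w`
#' gives the relative valuation of losses versus gains
#' `lambda = (U_b - U_l) / (U_w - U_b) = (1 - p) / p`. `p = 0` (rejecting even
#' the one-in-a-million loss) maps to `lambda = Inf`; accepting the first
#' ladder step gives `p = sqrt(0.5)` and hence `lambda = 0.414`, the most
#' risk-seeking value the ladder can express.
#'
#' @param p Indifference probability in `[0, 1)`; vectorised.
#' @return `lambda` in `(0, Inf]`.
#' @export
lambda_from_p <- function(p) {
  if (any(p < 0 | p >= 1, na.rm = TRUE)) {
    stop("indifference probability must lie in [0, 1)", call. = FALSE)
  }
  ifelse(p == 0, Inf, (1 - p) / p)
}

#' Loss-aversion record for one indifference point
#'
#' @param point An `sg_indiff`; undecidable points yield no record (`NULL`).
#' @return List with `lambda` and `lambda_prime`, or `NULL`.
#' @export
lambda_from_point <- function(point) {
  stopifnot(inherits(point, "sg_indiff"))
  if (point$status == "undecidable") return(NULL)
  lam <- lambda_from_p(point$p)
  list(lambda = lam, lambda_prime = lambda_prime(lam))
}

#' Bounded symmetric transform of loss aversion
#'
#' `lambda' = (lambda - 1) / (lambda + 1)` maps `(0, Inf]` onto `(-1, 1]`,
#' centred at 0 for risk neutrality; `lambda` and `1/lambda` map to values of
#' equal magnitude and opposite sign. `lambda = Inf` maps to 1.
#'
#' @param lambda Values in `(0, Inf]`; vectorised.
#' @return `lambda'` in `(-1, 1]`.
#' @export
lambda_prime <- function(lambda) {
  if (any(lambda <= 0, na.rm = TRUE)) {
    stop("lambda must be positive", call. = FALSE)
  }
  ifelse(is.infinite(lambda), 1, (lambda - 1) / (lambda + 1))
}

#' Inverse of the bounded loss-aversion transform
#'
#' @param lambda_prime Values in `(-1, 1]`; 1 maps back to `Inf`.
#' @return `lambda` in `(0, Inf]`.
#' @export
inverse_lambda_prime <- function(lambda_prime) {
  if (any(lambda_prime <= -1 | lambda_prime > 1, na.rm = TRUE)) {
    stop("lambda_prime must lie in (-1, 1]", call. = FALSE)
  }
  ifelse(lambda_prime == 1, Inf, (1 + lambda_prime) / (1 - lambda_prime))
}

#' Per-participant mean lambda' over a gamble subset
#'
#' Summaries of risk/inequality aversion average `lambda'` per participant
#' over the relevant adjacent gambles; a participant missing (undecidable)
#' any gamble in the subset is dropped. Infinite aversion enters as
#' `lambda' = 1`.
#'
#' @param points The `points` data.frame from [elicit_cohort()].
#' @param context `"personal"` or `"societal"`.
#' @param subset `"all"` (all four adjacent gambles), `"no_death"` (baselines
#'   D, C, B), or `"phys_health"` (gambles whose three states lie in A-D:
#'   baselines C and B).
#' @return Data frame with columns `id` and `mean_lambda_prime` (rows only for
#'   participants with the complete subset).
#' @export
participant_mean_lambda_prime <- function(points,
                                          context = c("personal", "societal"),
                                          subset = c("all", "no_death",
                                                     "phys_health")) {
  context <- match.arg(context)
  subset <- match.arg(subset)
  blk <- if (context == "personal") "adjacent_personal" else "adjacent_societal"
  baselines <- switch(subset,
                      all = c("E", "D", "C", "B"),
                      no_death = c("D", "C", "B"),
                      phys_health = c("C", "B"))
  sub <- points[points$block == blk & points$baseline %in% baselines, ,
                drop = FALSE]
  agg <- tapply(sub$lambda_prime, sub$id, function(v) {
    if (length(v) != length(baselines) || anyNA(v)) NA_real_ else mean(v)
  })
  out <- data.frame(id = names(agg), mean_lambda_prime = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[!is.na(out$mean_lambda_prime), , drop = FALSE]
}

.sg_quantile_type <- 8L  # median-unbiased quantile rule for [Q1, Q3]

.lambda_row_summary <- function(lam, qtype = .sg_quantile_type) {
  lam <- lam[!is.na(lam)]
  if (!length(lam)) {
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_, n = 0))
  }
  q <- stats::quantile(lam, c(0.25, 0.5, 0.75), type = qtype, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3], n = length(lam))
}

#' Summarise loss/inequality aversion across a cohort
#'
#' Produces a summary table over the adjacent gambles: one row per chained
#' gamble and three pooled rows over gamble subsets. Per-gamble rows report
#' the median and quartiles of `lambda` across participants who decided that
#' gamble. Pooled rows average `lambda'` per participant over the subset
#' (dropping participants who could not decide every relevant gamble),
#' back-transform the mean to `lambda`, and report median and quartiles
#' across participants. Proportion columns give the share of participants
#' with personal aversion (`lambda_p > 1`), societal aversion
#' (`lambda_s > 1`) and societal at least personal, computed on participants
#' contributing to both contexts. Correlation columns give Pearson's r
#' (with p-values) between the `lambda'` measures and the leftwards-positive
#' political alignment score.
#'
#' @param points The `points` data.frame from [elicit_cohort()].
#' @param respondents The cohort (used for political scores).
#' @param qtype Quantile type passed to [stats::quantile()]; default 8
#'   (median-unbiased).
#' @return Data frame with one row per gamble/subset.
#' @export
summarize_lambda <- function(points, respondents, qtype = .sg_quantile_type) {
  politics <- data.frame(
    id = vapply(respondents, function(r) as.character(r$id), character(1)),
    politics = vapply(respondents, function(r) r$political_score, numeric(1)),
    stringsAsFactors = FALSE)

  per_gamble <- lapply(c("E", "D", "C", "B"), function(b) {
    pers <- points[points$block == "adjacent_personal" &
                     points$baseline == b, , drop = FALSE]
    soc <- points[points$block == "adjacent_societal" &
                    points$baseline == b, , drop = FALSE]
    m <- merge(pers[!is.na(pers$lambda), c("id", "lambda", "lambda_prime")],
               soc[!is.na(soc$lambda), c("id", "lambda", "lambda_prime")],
               by = "id", suffixes = c("_p", "_s"))
    lose <- .sg_states[state_rank(b) - 1L]
    win <- .sg_states[state_rank(b) + 1L]
    .summary_row(sprintf("%s vs. %s/%s", b, win, lose),
                 pers$lambda, soc$lambda, m, politics, qtype)
  })

  pooled <- lapply(c("phys_health", "no_death", "all"), function(ss) {
    mp <- participant_mean_lambda_prime(points, "personal", ss)
    ms <- participant_mean_lambda_prime(points, "societal", ss)
    m <- merge(mp, ms, by = "id", suffixes = c("_p", "_s"))
    names(m)[2:3] <- c("lambda_prime_p", "lambda_prime_s")
    m$lambda_p <- inverse_lambda_prime(m$lambda_prime_p)
    m$lambda_s <- inverse_lambda_prime(m$lambda_prime_s)
    lab <- switch(ss, phys_health = "All gambles (phys health)",
                  no_death = "All gambles (no death)", all = "All gambles")
    .summary_row(lab, inverse_lambda_prime(mp$mean_lambda_prime),
                 inverse_lambda_prime(ms$mean_lambda_prime), m, politics, qtype)
  })

  out <- do.call(rbind, c(per_gamble, pooled))
  rownames(out) <- NULL
  out
}

.summary_row <- function(label, lam_p, lam_s, merged, politics, qtype) {
  sp <- .lambda_row_summary(lam_p, qtype)
  ss <- .lambda_row_summary(lam_s, qtype)
  prop_p <- prop_s <- prop_ge <- NA_real_
  r_ps <- p_ps <- r_p_pol <- p_p_pol <- r_s_pol <- p_s_pol <- NA_real_
  if (nrow(merged) >= 3L) {
    prop_p <- mean(merged$lambda_p > 1)
    prop_s <- mean(merged$lambda_s > 1)
    prop_ge <- mean(merged$lambda_s >= merged$lambda_p)
    sd_p <- stats::sd(merged$lambda_prime_p)
    sd_s <- stats::sd(merged$lambda_prime_s)
    if (sd_p > 0 && sd_s > 0) {
      ct <- pearson_r(merged$lambda_prime_p, merged$lambda_prime_s)
      r_ps <- ct$r; p_ps <- ct$p
    }
    mp <- merge(merged, politics, by = "id")
    if (nrow(mp) >= 3L && stats::sd(mp$politics) > 0) {
      if (sd_p > 0) {
        c1 <- pearson_r(mp$lambda_prime_p, mp$politics)
        r_p_pol <- c1$r; p_p_pol <- c1$p
      }
      if (sd_s > 0) {
        c2 <- pearson_r(mp$lambda_prime_s, mp$politics)
        r_s_pol <- c2$r; p_s_pol <- c2$p
      }
    }
  }
  data.frame(gamble = label,
             lambda_p_median = sp[["median"]], lambda_p_q1 = sp[["q1"]],
             lambda_p_q3 = sp[["q3"]], n_p = sp[["n"]],
             lambda_s_median = ss[["median"]], lambda_s_q1 = ss[["q1"]],
             lambda_s_q3 = ss[["q3"]], n_s = ss[["n"]],
             prop_p_averse = prop_p, prop_s_averse = prop_s,
             prop_s_ge_p = prop_ge,
             r_ps = r_ps, p_ps = p_ps,
             r_p_politics = r_p_pol, p_p_politics = p_p_pol,
             r_s_politics = r_s_pol, p_s_politics = p_s_pol,
             stringsAsFactors = FALSE)
}
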