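#' Expand a respondent's ladders into choice observations
#'
#' Every presented accept/reject ladder step of the selected contexts becomes
#' one binary observation (`cant_choose` steps are omitted). For the default
#' personal context this yields the 8 personal gambles (4 adjacent + 4
#' non-adjacent) used by the per-participant discrete-choice fit.
#'
#' @param resp An `sg_respondent`.
#' @param contexts Character vector of contexts to include.
#' @return Data frame with columns `id`, `gamble_index`, `baseline`, `win`,
#'   `lose`, `p_loss` (numeric), `chose_gamble` (logical), in presentation
#'   order.
#' @export
expand_ladders <- function(resp, contexts = "personal") {
  stopifnot(inherits(resp, "sg_respondent"))
  rows <- lapply(seq_along(resp$ladders), function(gi) {
    l <- resp$ladders[[gi]]
    if (!(l$gamble$context %in% contexts)) return(NULL)
    keep <- l$decisions != "cant_choose"
    if (!any(keep)) return(NULL)
    data.frame(id = as.character(resp$id), gamble_index = gi,
               baseline = l$gamble$baseline, win = l$gamble$win,
               lose = l$gamble$lose, p_loss = l$p[keep],
               chose_gamble = l$decisions[keep] == "accept",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(id = character(0),
                                      gamble_index = integer(0),
                                      baseline = character(0),
                                      win = character(0), lose = character(0),
                                      p_loss = numeric(0),
                                      chose_gamble = logical(0))
  out
}

# Gamble expected utility for a full state-utility vector (estimation scale,
# U_F = 0, U_E = 1), optionally CPT-weighting the loss probability.
.gamble_eu <- function(obs, u, params = NULL) {
  p <- obs$p_loss
  if (!is.null(params)) p <- effective_probability(p, params)
  p * u[state_rank(obs$lose)] + (1 - p) * u[state_rank(obs$win)]
}

.choice_nll <- function(theta, obs, params = NULL,
                        log_sigma_bounds = c(log(1e-6), log(1e6))) {
  log_sigma <- min(max(theta[1], log_sigma_bounds[1]), log_sigma_bounds[2])
  sigma <- exp(log_sigma)
  u <- c(0, 1, theta[2], theta[3], theta[4], theta[5])
  d <- sigma * (.gamble_eu(obs, u, params) - u[state_rank(obs$baseline)])
  ll <- ifelse(obs$chose_gamble,
               stats::plogis(d, log.p = TRUE),
               stats::plogis(-d, log.p = TRUE))
  -sum(ll)
}

#' Fit the per-participant binomial-logit choice model
#'
#' Maximum-likelihood fit of `P(choose gamble) = exp(sigma * EU_gamble) /
#' (exp(sigma * EU_gamble) + exp(sigma * U_baseline))` over a participant's
#' pooled personal-gamble observations, with `EU_gamble = p*U_lose +
#' (1-p)*U_win`, anchors `U_F = 0, U_E = 1` held fixed, and free parameters
#' `sigma` (choice sensitivity) and the utilities of states D, C, B, A.
#' Utilities are unconstrained during optimisation; monotonicity violations
#' are flagged post hoc rather than hidden. The optimiser is multi-started
#' from the chained-gamble curve (when finite) and from the risk-neutral
#' linear curve; the best likelihood wins. Degenerate all-accept or
#' all-reject data leave `sigma` unidentified: the fit is returned with
#' `converged = FALSE` and `sigma` at its bound rather than raising.
#'
#' @param observations Data frame from [expand_ladders()] for one
#'   participant; needs at least 8 rows for a meaningful fit.
#' @param init Optional `sg_curve` (estimation anchoring) used as a starting
#'   value.
#' @param params Optional `cpt_params`: fit the model with CPT-weighted loss
#'   probabilities (used for model-comparison residuals).
#' @param sigma_bounds Length-2 positive bounds on `sigma`.
#' @param reltol Convergence tolerance on the log-likelihood.
#' @return Object of class `sg_choice_fit`: `id`, `sigma`, `utilities`
#'   (named, estimation scale), `loglik`, `mcfadden_r2`, `pct_correct`,
#'   `converged`, `monotone`, `n_obs`.
#' @export
fit_participant <- function(observations, init = NULL, params = NULL,
                            sigma_bounds = c(1e-6, 1e6), reltol = 1e-8) {
  obs <- observations
  id <- if (nrow(obs)) obs$id[1] else NA_character_
  lsb <- log(sigma_bounds)
  degenerate <- nrow(obs) < 2L || length(unique(obs$chose_gamble)) < 2L
  starts <- list(c(0, 2, 3, 4, 5))  # linear (risk-neutral) curve, sigma = 1
  if (!is.null(init)) {
    ui <- init$utilities[c("D", "C", "B", "A")]
    if (all(is.finite(ui))) starts <- c(list(c(0, unname(ui))), starts)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, .choice_nll, obs = obs, params = params,
                   log_sigma_bounds = lsb, method = "L-BFGS-B",
                   lower = c(lsb[1], rep(-Inf, 4)),
                   upper = c(lsb[2], rep(Inf, 4)),
                   control = list(maxit = 500, factr = reltol / 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    best <- list(par = starts[[1]], value = .choice_nll(starts[[1]], obs,
                                                        params, lsb),
                 convergence = 1L)
  }
  u <- c(F = 0, E = 1, D = best$par[2], C = best$par[3], B = best$par[4],
         A = best$par[5])
  fit <- structure(list(id = id,
                        sigma = exp(min(max(best$par[1], lsb[1]), lsb[2])),
                        utilities = u,
                        loglik = -best$value,
                        converged = best$convergence == 0L && !degenerate,
                        monotone = !is.unsorted(u),
                        n_obs = nrow(obs),
                        cpt = params),
                   class = "sg_choice_fit")
  fit$mcfadden_r2 <- mcfadden_r2(fit, obs)
  fit$pct_correct <- pct_correct(fit, obs)
  fit
}

#' @export
print.sg_choice_fit <- function(x, ...) {
  cat(sprintf("<choice fit %s> sigma = %.3g, r2 = %.3f, %s\n",
              as.character(x$id), x$sigma, x$mcfadden_r2,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$utilities, 4))
  invisible(x)
}

#' Predicted acceptance probabilities
#'
#' @param fit An `sg_choice_fit`.
#' @param observations Data frame of observations.
#' @param params Optional `cpt_params` (defaults to the weighting the fit was
#'   estimated under).
#' @return Numeric vector of `P(choose gamble)`.
#' @export
predict_acceptance <- function(fit, observations, params = NULL) {
  stopifnot(inherits(fit, "sg_choice_fit"))
  if (is.null(params)) params <- fit$cpt
  u <- unname(fit$utilities)
  d <- fit$sigma * (.gamble_eu(observations, u, params) -
                      u[state_rank(observations$baseline)])
  stats::plogis(d)
}

#' McFadden's pseudo-r-squared
#'
#' `1 - loglik / loglik_null` with the null the coin-flip model
#' (`P = 0.5` for every observation); 0 when the fit is no better than
#' chance, approaching 1 under perfect separation.
#'
#' @param fit An `sg_choice_fit`.
#' @param observations The observations the fit was estimated on.
#' @return Numeric scalar.
#' @export
mcfadden_r2 <- function(fit, observations) {
  n <- nrow(observations)
  if (n == 0L) stop("no observations", call. = FALSE)
  1 - fit$loglik / (n * log(0.5))
}

#' Proportion of choices correctly predicted
#'
#' A choice is counted correct when the predicted probability is on the same
#' side of 0.5 as the observed choice; exact ties (`P = 0.5`) count as
#' incorrect.
#'
#' @inheritParams mcfadden_r2
#' @return Fraction in `[0, 1]`.
#' @export
pct_correct <- function(fit, observations) {
  pr <- predict_acceptance(fit, observations)
  mean((pr > 0.5) == observations$chose_gamble & pr != 0.5)
}

#' Fit choice models for every respondent in a cohort
#'
#' @param respondents List of `sg_respondent`.
#' @param curves Optional `curves` element from [elicit_cohort()]; each
#'   participant's chained personal estimation curve seeds the optimiser.
#' @param params Optional `cpt_params` for CPT-weighted fits.
#' @return Named list of `sg_choice_fit` (NULL for participants with no
#'   usable observations), names = participant ids.
#' @export
fit_cohort <- function(respondents, curves = NULL, params = NULL) {
  fits <- lapply(respondents, function(r) {
    obs <- expand_ladders(r)
    if (nrow(obs) == 0L) return(NULL)
    id <- as.character(r$id)
    init <- if (!is.null(curves) && !is.null(curves[[id]])) {
      curves[[id]]$personal$estimation
    }
    fit_participant(obs, init = init, params = params)
  })
  names(fits) <- vapply(respondents, function(r) as.character(r$id),
                        character(1))
  fits
}
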