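#' Specify a simulated decision agent
#'
#' An agent is defined by strictly increasing true utilities over the six
#' states (estimation scale, `U_F = 0, U_E = 1`), a choice sensitivity
#' `sigma` (`Inf` for a deterministic expected-utility maximiser; finite
#' values give logistic choice noise), optional CPT probability-weighting
#' parameters, a societal-context loss-weighting multiplier (agents are more
#' cautious when outcomes affect others), an extra multiplier applied to
#' societal gambles whose loss arm is death, and a per-step `cant_choose`
#' rate.
#'
#' @param true_utilities Named numeric over F, E, D, C, B, A, strictly
#'   increasing.
#' @param sigma Positive choice sensitivity, or `Inf` for deterministic
#'   choice (ties accepted).
#' @param cpt Optional `cpt_params`; identity parameters reproduce the
#'   expected-utility agent exactly.
#' @param societal_multiplier Factor >= 1 applied to the loss term in
#'   societal-context decisions.
#' @param death_multiplier Factor >= 1 additionally applied in societal
#'   decisions whose lose state is death.
#' @param cant_choose_rate Per-step probability of answering "can't choose".
#' @param seed Optional per-agent seed recorded for reproducibility.
#' @return Object of class `sg_agent`.
#' @export
agent_spec <- function(true_utilities, sigma = Inf, cpt = NULL,
                       societal_multiplier = 1, death_multiplier = 1,
                       cant_choose_rate = 0, seed = NULL) {
  u <- true_utilities[.sg_states]
  if (anyNA(u) || any(diff(u) <= 0)) {
    stop("true_utilities must be named F..A and strictly increasing",
         call. = FALSE)
  }
  if (!(sigma > 0)) stop("sigma must be positive (or Inf)", call. = FALSE)
  if (societal_multiplier < 1 || death_multiplier < 1) {
    stop("context multipliers must be >= 1", call. = FALSE)
  }
  if (cant_choose_rate < 0 || cant_choose_rate >= 1) {
    stop("cant_choose_rate must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(cpt)) stopifnot(inherits(cpt, "cpt_params"))
  structure(list(true_utilities = u, sigma = sigma, cpt = cpt,
                 societal_multiplier = societal_multiplier,
                 death_multiplier = death_multiplier,
                 cant_choose_rate = cant_choose_rate, seed = seed),
            class = "sg_agent")
}

#' Geometric-decrement utilities from a target loss aversion
#'
#' Builds a utility curve whose adjacent-state increments shrink by the
#' factor `1/lambda` at each step up the scale, so that every adjacent
#' gamble has true loss aversion exactly `lambda` and true indifference
#' probability `1 / (1 + lambda)`.
#'
#' @param lambda Positive loss-aversion value.
#' @return Named utilities over F..A (estimation scale).
#' @export
utilities_from_lambda <- function(lambda) {
  if (!(lambda > 0)) stop("lambda must be positive", call. = FALSE)
  inc <- lambda^(-(0:4))
  stats::setNames(c(0, cumsum(inc)), .sg_states)
}

# Signed advantage of the gamble over the certain baseline, with the
# societal-context loss multiplier and optional CPT weighting.
.gamble_advantage <- function(agent, gamble, p) {
  u <- agent$true_utilities
  ub <- u[[gamble$baseline]]; uw <- u[[gamble$win]]; ul <- u[[gamble$lose]]
  if (is.null(agent$cpt)) {
    wl <- p; wg <- 1 - p
  } else {
    wl <- cpt_weight(p, agent$cpt); wg <- cpt_weight(1 - p, agent$cpt)
  }
  m <- 1
  if (gamble$context == "societal") {
    m <- agent$societal_multiplier
    if (gamble$lose == "F") m <- m * agent$death_multiplier
  }
  wg * (uw - ub) - m * wl * (ub - ul)
}

#' Simulate one choice ladder
#'
#' Walks the descending probability grid. A deterministic agent accepts as
#' soon as the gamble's (weighted) expected utility is at least the baseline
#' utility (exact ties accepted); a stochastic agent accepts each step
#' independently with the logit probability at its sensitivity. Can't-choose
#' events occur independently per step; two in a row (or one at the lowest
#' grid value) end the ladder as undecidable. Uses the current RNG state;
#' seed control belongs to the cohort simulator's per-agent substreams.
#'
#' @param agent An `sg_agent`.
#' @param gamble An `sg_gamble` over states in the agent's utility map.
#' @return An `sg_ladder`.
#' @export
simulate_ladder <- function(agent, gamble) {
  stopifnot(inherits(agent, "sg_agent"), inherits(gamble, "sg_gamble"))
  decisions <- character(0)
  prev_cc <- FALSE
  for (i in seq_along(.sg_grid_values)) {
    if (agent$cant_choose_rate > 0 &&
        stats::runif(1) < agent$cant_choose_rate) {
      decisions <- c(decisions, "cant_choose")
      if (prev_cc || i == 8L) break
      prev_cc <- TRUE
      next
    }
    prev_cc <- FALSE
    adv <- .gamble_advantage(agent, gamble, .sg_grid_values[i])
    accept <- if (is.infinite(agent$sigma)) {
      adv >= -1e-12
    } else {
      stats::runif(1) < stats::plogis(agent$sigma * adv)
    }
    decisions <- c(decisions, if (accept) "accept" else "reject")
    if (accept) break
  }
  ladder_response(gamble, decisions)
}

#' Simulate vignette life-satisfaction ratings
#'
#' Integer ratings centred on (A, B, C, D, E) = (10, 8, 6, 4, 2) with
#' configurable dispersion; in the absence of an order-violation event the
#' ratings are forced monotone (A >= ... >= E). With probability
#' `violation_rate` one adjacent pair is swapped to produce a strict
#' out-of-order response.
#'
#' @param dispersion SD of the integer jitter; 0 gives the exact medians.
#' @param violation_rate Probability of an order violation.
#' @return Named integer ratings A-E.
#' @export
make_vignette_ratings <- function(dispersion = 0, violation_rate = 0) {
  base <- c(A = 10, B = 8, C = 6, D = 4, E = 2)
  v <- base
  if (dispersion > 0) {
    v <- pmin(10, pmax(0, round(base + stats::rnorm(5, 0, dispersion))))
    v <- sort(v, decreasing = TRUE)
    names(v) <- names(base)
  }
  if (violation_rate > 0 && stats::runif(1) < violation_rate) {
    j <- sample.int(4L, 1L)
    if (v[j] == v[j + 1L]) v[j + 1L] <- max(0, v[j + 1L] - 1L)
    v[c(j, j + 1L)] <- v[c(j + 1L, j)]
  }
  v
}

#' Default synthetic-population parameters
#'
#' The defaults emulate the study conditions of a 300-respondent UK survey:
#' personal loss aversion drawn as truncated-normal `lambda'` (mean 0.33,
#' SD 0.34); a lognormal societal loss-weighting multiplier centred at 2.3
#' (the ratio of pooled societal to personal median aversion); a lognormal
#' extra multiplier centred at 5 on societal death gambles (which show far
#' stronger aversion than living-state societal gambles, while personal death
#' gambles show none); lognormal choice sensitivity centred at 3; a 1%
#' per-step can't-choose rate; vignette jitter with a 5.1% order-violation
#' rate; and party shares matching the recruitment quotas.
#'
#' @param ... Named overrides of any default.
#' @return List of population parameters for [simulate_cohort()].
#' @export
cohort_population <- function(...) {
  pop <- list(
    lambda_prime_mean = 0.33, lambda_prime_sd = 0.34,
    societal_multiplier_meanlog = log(2.3), societal_multiplier_sdlog = 0.5,
    death_multiplier_meanlog = log(5), death_multiplier_sdlog = 0.8,
    sigma_meanlog = log(3), sigma_sdlog = 0.8,
    deterministic = FALSE,
    cpt = NULL,
    cant_choose_rate = 0.01,
    vignette_dispersion = 0.7, violation_rate = 0.051,
    parties = c(Conservative = 54, Green = 22, Labour = 141,
                `Liberal Democrats` = 26, `Reform UK` = 37, SNP = 10,
                Other = 10) / 300,
    party_politics_mean = c(Conservative = 2.2, Green = 4.0, Labour = 3.8,
                            `Liberal Democrats` = 3.2, `Reform UK` = 2.0,
                            SNP = 3.8, Other = 3.0),
    age_bands = c(`18-24` = 36, `25-34` = 50, `35-44` = 50, `45-54` = 50,
                  `55+` = 114) / 300,
    sexes = c(female = 157, male = 143) / 300)
  over <- list(...)
  bad <- setdiff(names(over), names(pop))
  if (length(bad)) stop("unknown population parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  pop[names(over)] <- over
  pop
}

# Per-agent substream seed: stable under cohort-size changes, < 2^31.
.agent_seed <- function(seed, i) {
  as.integer(((seed %% 100000) * 20011 + i * 7919 + 1) %% 2147483647)
}

#' Simulate a survey cohort with known ground truth
#'
#' Generates `n` respondents, each completing the 12-gamble design (4
#' adjacent personal, 4 adjacent societal, 4 non-adjacent personal drawn
#' uniformly from the valid triples with states up to 3 steps apart and at
#' least one non-adjacent arm), plus vignette ratings, demographics and the
#' five-item political scale. All randomness flows from per-agent substreams
#' derived from `seed`, so each agent's record is identical whatever the
#' cohort size.
#'
#' @param n Number of respondents.
#' @param population Parameter list from [cohort_population()].
#' @param seed Master seed.
#' @return List with `respondents` (list of `sg_respondent`) and
#'   `ground_truth` (data frame of every agent's true parameters).
#' @export
simulate_cohort <- function(n = 300, population = cohort_population(),
                            seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  pop <- population
  triples <- nonadjacent_triples()
  respondents <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.agent_seed(seed, i))
    id <- sprintf("S%04d", i)
    condition <- sample(c("gambles_first", "ls_first"), 1L)
    party <- sample(names(pop$parties), 1L, prob = pop$parties)
    age_band <- sample(names(pop$age_bands), 1L, prob = pop$age_bands)
    sex <- sample(names(pop$sexes), 1L, prob = pop$sexes)
    pol_mu <- pop$party_politics_mean[[party]]
    political_items <- pmin(5L, pmax(1L, round(stats::rnorm(5, pol_mu, 1))))

    lp <- stats::rnorm(1, pop$lambda_prime_mean, pop$lambda_prime_sd)
    lp <- min(max(lp, -0.99), 0.99)
    lambda_true <- inverse_lambda_prime(lp)
    sigma <- if (isTRUE(pop$deterministic)) Inf else {
      stats::rlnorm(1, pop$sigma_meanlog, pop$sigma_sdlog)
    }
    sm <- max(1, stats::rlnorm(1, pop$societal_multiplier_meanlog,
                               pop$societal_multiplier_sdlog))
    dm <- max(1, stats::rlnorm(1, pop$death_multiplier_meanlog,
                               pop$death_multiplier_sdlog))
    agent <- agent_spec(utilities_from_lambda(lambda_true), sigma = sigma,
                        cpt = pop$cpt, societal_multiplier = sm,
                        death_multiplier = dm,
                        cant_choose_rate = pop$cant_choose_rate,
                        seed = .agent_seed(seed, i))

    ratings <- make_vignette_ratings(pop$vignette_dispersion,
                                     pop$violation_rate)
    design <- c(adjacent_gambles("personal"), adjacent_gambles("societal"),
                lapply(sample.int(nrow(triples), 4L), function(k) {
                  gamble_spec(triples$baseline[k], triples$win[k],
                              triples$lose[k], "personal",
                              "nonadjacent_personal")
                }))
    ladders <- lapply(design, function(g) simulate_ladder(agent, g))
    respondents[[i]] <- respondent(id = id, condition = condition,
                                   age_band = age_band, sex = sex,
                                   party = party,
                                   political_items = political_items,
                                   vignette_ratings = ratings,
                                   ladders = ladders)
    truth[[i]] <- data.frame(
      id = id, condition = condition, party = party,
      lambda_true = lambda_true, lambda_prime_true = lp,
      sigma = sigma, societal_multiplier = sm, death_multiplier = dm,
      delta = if (is.null(pop$cpt)) NA_real_ else pop$cpt$delta,
      gamma = if (is.null(pop$cpt)) NA_real_ else pop$cpt$gamma,
      cant_choose_rate = pop$cant_choose_rate,
      U_D = agent$true_utilities[["D"]], U_C = agent$true_utilities[["C"]],
      U_B = agent$true_utilities[["B"]], U_A = agent$true_utilities[["A"]],
      stringsAsFactors = FALSE)
  }
  list(respondents = respondents, ground_truth = do.call(rbind, truth))
}
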