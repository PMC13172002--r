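# Shared fixtures: deterministic agents, small cohorts, hand-built ladders.

det_agent <- function(lambda, ...) {
  agent_spec(utilities_from_lambda(lambda), sigma = Inf, ...)
}

interior_point <- function(p) {
  structure(list(p = p, status = "interior"), class = "sg_indiff")
}

# Quiet deterministic cohort: no choice noise, no can't-choose, exact ratings.
det_population <- function(...) {
  cohort_population(deterministic = TRUE, cant_choose_rate = 0,
                    vignette_dispersion = 0, violation_rate = 0, ...)
}

# Noise-free stochastic-population variant used by fit-quality tests.
quiet_population <- function(...) {
  cohort_population(cant_choose_rate = 0, violation_rate = 0, ...)
}

# The 8-gamble personal design used by choice-model fixtures.
personal_design <- function() {
  tr <- nonadjacent_triples()
  c(adjacent_gambles("personal"),
    lapply(c(1L, 5L, 9L, 13L), function(k) {
      gamble_spec(tr$baseline[k], tr$win[k], tr$lose[k],
                  "personal", "nonadjacent_personal")
    }))
}

# Pool accept/reject observations from `reps` simulated runs of a design.
simulate_observations <- function(agent, design, reps = 1, id = "X") {
  do.call(rbind, lapply(seq_len(reps), function(r) {
    rows <- lapply(seq_along(design), function(gi) {
      l <- simulate_ladder(agent, design[[gi]])
      keep <- l$decisions != "cant_choose"
      if (!any(keep)) return(NULL)
      data.frame(id = id, gamble_index = gi,
                 baseline = design[[gi]]$baseline, win = design[[gi]]$win,
                 lose = design[[gi]]$lose, p_loss = l$p[keep],
                 chose_gamble = l$decisions[keep] == "accept",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
}

# Grid-snapping oracle: the lambda the ladder procedure must elicit for a
# deterministic agent with true indifference probability p_true, computed by
# direct enumeration of the bracketing grid step (independent of the ladder
# walk itself).
snapped_lambda_oracle <- function(p_true) {
  grid <- unname(probability_grid())
  accepted <- grid[grid <= p_true + 1e-12]   # tie accepted
  p_acc <- if (length(accepted)) max(accepted) else 0
  rejected <- grid[grid > p_true + 1e-12]
  p_rej <- if (length(rejected)) min(rejected) else 1
  p_mid <- sqrt(p_acc * p_rej)
  if (p_mid == 0) Inf else (1 - p_mid) / p_mid
}

# The midpoint lattice of elicitable lambda values for deterministic agents.
lambda_lattice <- function() {
  grid <- c(1, unname(probability_grid()), 0)
  mids <- sqrt(grid[-length(grid)] * grid[-1])
  c((1 - mids[mids > 0]) / mids[mids > 0], Inf)
}
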