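test_that("indifference points are log-scale midpoints with correct statuses", {
  g <- gamble_spec("E", "D", "F", "personal", "adjacent_personal")
  ip <- indifference_probability(ladder_response(g, c("reject", "accept")))
  expect_equal(ip$p, sqrt(0.5 * 0.2), tolerance = 1e-12)
  expect_identical(ip$status, "interior")

  ip0 <- indifference_probability(ladder_response(g, rep("reject", 8)))
  expect_identical(ip0$p, 0)
  expect_identical(ip0$status, "infinite_aversion")

  ip1 <- indifference_probability(ladder_response(g, "accept"))
  expect_equal(ip1$p, sqrt(0.5), tolerance = 1e-12)
  expect_identical(ip1$status, "maximal_tolerance")

  ipu <- indifference_probability(
    ladder_response(g, c("cant_choose", "cant_choose")))
  expect_identical(ipu$status, "undecidable")
  expect_true(is.na(ipu$p))
})

test_that("chained solve reproduces closed-form utility curves", {
  # risk-neutral chain: equally spaced utilities
  cv <- chained_utilities(lapply(rep(0.5, 4), interior_point))
  expect_equal(unname(cv$utilities), 0:5)
  expect_equal(unname(rescale_to_reporting(cv)$utilities),
               seq(0, 1, by = 0.2))
  # common interior point 0.31623: hand-substituted sequence
  cv2 <- chained_utilities(lapply(rep(0.31623, 4), interior_point))
  expect_equal(unname(cv2$utilities),
               c(0, 1, 1.4625, 1.6764, 1.7753, 1.8211), tolerance = 1e-4)
  expect_equal(rescale_to_reporting(cv2)$utilities[["E"]], 0.5491,
               tolerance = 1e-4)
  # infinite aversion on the death gamble: exactly flat first step; each
  # later increment is proportional to the previous one, so flatness
  # propagates exactly up the chain
  cv3 <- chained_utilities(lapply(c(0, 0.5, 0.5, 0.5), interior_point))
  expect_identical(cv3$utilities[["D"]], cv3$utilities[["E"]])
  expect_identical(cv3$utilities[["D"]], 1)
  expect_equal(unname(cv3$utilities), c(0, 1, 1, 1, 1, 1))
  # inadmissible inputs
  expect_error(chained_utilities(lapply(c(0.5, 1, 0.5, 0.5), interior_point)),
               "p >= 1")
  und <- structure(list(p = NA_real_, status = "undecidable"),
                   class = "sg_indiff")
  expect_error(chained_utilities(list(und, interior_point(0.5),
                                      interior_point(0.5),
                                      interior_point(0.5))),
               "undecidable")
})

test_that("every solved state satisfies the indifference relation to 1e-12", {
  set.seed(42)
  for (rep in 1:50) {
    p <- runif(4, 0, sqrt(0.5))
    p[runif(4) < 0.15] <- 0  # mix in flat steps
    u <- chained_utilities(lapply(p, interior_point))$utilities
    for (k in 1:4) {
      resid <- u[k + 1] - (p[k] * u[k] + (1 - p[k]) * u[k + 2])
      expect_lt(abs(resid), 1e-12)
    }
    expect_true(all(diff(u) >= -1e-12))
  }
})

test_that("reporting rescale divides by U_A, preserves order, is idempotent", {
  cv <- chained_utilities(lapply(rep(0.3, 4), interior_point))
  rep1 <- rescale_to_reporting(cv)
  expect_equal(rep1$utilities[["A"]], 1)
  expect_equal(rescale_to_reporting(rep1)$utilities, rep1$utilities)
  flat <- structure(list(utilities = c(F = 0, E = 1, D = 1, C = 1, B = 1,
                                       A = 1), anchoring = "estimation"),
                    class = "sg_curve")
  expect_equal(unname(rescale_to_reporting(flat)$utilities),
               c(0, 1, 1, 1, 1, 1))
  allflat <- structure(list(utilities = c(F = 0, E = 0, D = 0, C = 0, B = 0,
                                          A = 0), anchoring = "estimation"),
                       class = "sg_curve")
  expect_error(rescale_to_reporting(allflat), "degenerate")
})

test_that("living-states chain solves the coupled no-death system exactly", {
  set.seed(7)
  for (rep in 1:30) {
    p <- runif(3, 0, sqrt(0.5))
    u <- living_utilities(lapply(p, interior_point))$utilities
    expect_equal(u[["E"]], 0); expect_equal(u[["A"]], 1)
    expect_lt(abs(u[["D"]] - (p[1] * u[["E"]] + (1 - p[1]) * u[["C"]])), 1e-12)
    expect_lt(abs(u[["C"]] - (p[2] * u[["D"]] + (1 - p[2]) * u[["B"]])), 1e-12)
    expect_lt(abs(u[["B"]] - (p[3] * u[["C"]] + (1 - p[3]) * u[["A"]])), 1e-12)
    expect_true(all(diff(u) >= -1e-12))
  }
  # risk-neutral case: equally spaced on [0, 1]
  lin <- living_utilities(lapply(rep(0.5, 3), interior_point))
  expect_equal(unname(lin$utilities), seq(0, 1, by = 0.25))
})

test_that("lambda transforms: closed forms, lattice values and round trips", {
  expect_equal(lambda_from_p(0.5), 1)
  expect_equal(lambda_prime(1), 0)
  expect_equal(lambda_from_p(0.31623), 2.1623, tolerance = 1e-4)
  expect_equal(lambda_from_p(0.031623), 30.62, tolerance = 1e-3)
  expect_equal(lambda_from_p(0.0031623), 315.2, tolerance = 1e-3)
  expect_identical(lambda_from_p(0), Inf)
  expect_identical(lambda_prime(Inf), 1)
  expect_identical(inverse_lambda_prime(1), Inf)
  expect_equal(inverse_lambda_prime(0.5), 3)

  set.seed(1)
  lam <- exp(runif(200, log(1e-4), log(1e4)))
  expect_equal(inverse_lambda_prime(lambda_prime(lam)), lam,
               tolerance = 1e-12)
  # lambda and 1/lambda map to opposite equal magnitudes
  expect_equal(lambda_prime(lam), -lambda_prime(1 / lam), tolerance = 1e-12)

  expect_error(lambda_prime(0), "positive")
  expect_error(inverse_lambda_prime(-1), "\\(-1, 1\\]")
  expect_error(lambda_from_p(1), "\\[0, 1\\)")

  pt <- interior_point(0.5)
  expect_equal(lambda_from_point(pt)$lambda, 1)
  und <- structure(list(p = NA_real_, status = "undecidable"),
                   class = "sg_indiff")
  expect_null(lambda_from_point(und))
})

test_that("participant-level summaries pool mean lambda-prime then back-transform", {
  pts <- data.frame(
    id = "p1", gamble_index = 1:4, context = "personal",
    block = "adjacent_personal", label = "x",
    baseline = c("E", "D", "C", "B"), p = 0.3, status = "interior",
    lambda = NA_real_, lambda_prime = c(0.2, 0.4, 0.2, 0.4),
    stringsAsFactors = FALSE)
  m <- participant_mean_lambda_prime(pts, "personal", "all")
  expect_equal(m$mean_lambda_prime, 0.3)
  expect_equal(inverse_lambda_prime(m$mean_lambda_prime), 13 / 7,
               tolerance = 1e-12)  # 1.857
  # an undecidable gamble in the subset drops the participant
  pts$lambda_prime[2] <- NA
  expect_equal(nrow(participant_mean_lambda_prime(pts, "personal", "all")), 0)
  # ... but not from subsets that exclude the undecidable gamble
  expect_equal(
    participant_mean_lambda_prime(pts, "personal", "phys_health")$mean_lambda_prime,
    0.3)
})

test_that("a risk-neutral cohort snaps to the 0.414 maximal-tolerance lattice value", {
  pop <- det_population(lambda_prime_mean = 0, lambda_prime_sd = 0,
                        societal_multiplier_meanlog = 0,
                        societal_multiplier_sdlog = 0,
                        death_multiplier_meanlog = 0,
                        death_multiplier_sdlog = 0)
  sim <- simulate_cohort(12, pop, seed = 4)
  el <- elicit_cohort(sim$respondents)
  tab <- summarize_lambda(el$points, sim$respondents)
  per_gamble <- tab[1:4, ]
  # accept-at-1/2 snaps to p = sqrt(0.5), lambda = (1 - p)/p = 0.414
  expect_equal(per_gamble$lambda_p_median,
               rep((1 - sqrt(0.5)) / sqrt(0.5), 4), tolerance = 1e-9)
  expect_equal(per_gamble$lambda_s_median,
               rep((1 - sqrt(0.5)) / sqrt(0.5), 4), tolerance = 1e-9)
})

test_that("lambda summaries drop participants with undecidable relevant gambles", {
  sim <- simulate_cohort(10, det_population(), seed = 8)
  r <- sim$respondents
  # force one undecidable adjacent personal gamble for participant 1
  g1 <- r[[1]]$ladders[[1]]$gamble
  r[[1]]$ladders[[1]] <- ladder_response(g1, c("cant_choose", "cant_choose"))
  el <- elicit_cohort(r)
  tab <- summarize_lambda(el$points, r)
  all_row <- tab[tab$gamble == "All gambles", ]
  expect_equal(all_row$n_p, 9)             # participant 1 dropped
  expect_equal(tab$n_p[tab$gamble == "E vs. D/F"], 9)
  expect_equal(tab$n_p[tab$gamble == "D vs. C/E"], 10)  # still decidable
  # summary medians are invariant under participant permutation
  perm <- r[c(4, 2, 9, 1, 10, 3, 6, 5, 8, 7)]
  tab2 <- summarize_lambda(elicit_cohort(perm)$points, perm)
  expect_equal(tab2$lambda_p_median, tab$lambda_p_median)
  expect_equal(tab2$lambda_s_median, tab$lambda_s_median)
})
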