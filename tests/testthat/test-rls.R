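lin_fn <- function() ls_utility_function(c(0, 10), c(0, 10))
conc_fn <- function() {
  ls_utility_function(c(2, 4, 6, 8, 10), c(0.549, 0.803, 0.921, 0.975, 1))
}
uk_dist <- function() binned_ls_distribution(c(0.06, 0.10, 0.50, 0.34))

test_that("piecewise-linear evaluation matches hand interpolation", {
  cv <- structure(list(utilities = c(E = 0, D = 0.25, C = 0.5, B = 0.75,
                                     A = 1), anchoring = "living"),
                  class = "sg_curve")
  fn <- curve_to_ls_function(cv, c(E = 2, D = 4, C = 6, B = 8, A = 10))
  expect_equal(evaluate_ls(fn, 5), (0.25 + 0.5) / 2)  # midpoint of D and C
  expect_equal(evaluate_ls(fn, c(2, 6, 10)), c(0, 0.5, 1))
  # constant slope everywhere, extended below the lowest knot
  expect_equal(diff(evaluate_ls(fn, 0:10)), rep(0.125, 10))
  # above the top knot the function is constant
  hi <- ls_utility_function(c(2, 5), c(0, 1))
  expect_equal(evaluate_ls(hi, c(5, 7, 10)), c(1, 1, 1))

  # hand-computed segment arithmetic at the bin representatives
  fn2 <- conc_fn()
  expect_equal(evaluate_ls(fn2, c(2, 5.5, 7.5, 9.5)),
               c(0.549,
                 0.803 + 0.75 * (0.921 - 0.803),
                 0.921 + 0.75 * (0.975 - 0.921),
                 0.975 + 0.75 * (1 - 0.975)),
               tolerance = 1e-12)
  expect_error(ls_utility_function(c(2, 2, 6), c(0, 1, 2)), "increasing")
  expect_error(ls_utility_function(c(2, 4, 6), c(0, 1, 0.5)), "nondecreasing")
})

test_that("reference normalisation yields unit SD and is scale invariant", {
  d <- uk_dist()
  fn <- conc_fn()
  nf <- normalize_by_reference(fn, d)
  u <- evaluate_ls(nf, d$representative_ls)
  mu <- sum(d$shares * u)
  expect_equal(sqrt(sum(d$shares * (u - mu)^2)), 1, tolerance = 1e-12)
  # affine-rescaled input differs after normalisation by a constant only
  aff <- ls_utility_function(fn$ls, 3.7 * fn$utility + 2.2)
  naff <- normalize_by_reference(aff, d)
  x <- seq(0, 10, by = 0.5)
  expect_equal(diff(evaluate_ls(naff, x)), diff(evaluate_ls(nf, x)),
               tolerance = 1e-9)
  flat <- ls_utility_function(c(0, 10), c(1, 1))
  expect_error(normalize_by_reference(flat, d), "zero SD")
  degen <- binned_ls_distribution(c(0, 0, 1, 0))
  expect_error(normalize_by_reference(fn, degen), "zero SD")
})

test_that("expected utility is the share-weighted evaluation", {
  d <- uk_dist()
  expect_equal(expected_utility(lin_fn(), d), 7.65)
  degen <- binned_ls_distribution(c(0, 0, 1, 0))
  expect_equal(expected_utility(conc_fn(), degen),
               evaluate_ls(conc_fn(), 7.5))
  two <- binned_ls_distribution(c(0.5, 0, 0.5, 0))
  expect_equal(expected_utility(lin_fn(), two), (2 + 7.5) / 2)
})

test_that("certainty equivalents invert monotone curves, Jensen-style", {
  expect_equal(as.numeric(certainty_equivalent(lin_fn(), 6.3)), 6.3,
               tolerance = 1e-8)
  # sqrt-shaped knots: E[U] = 2.5 on {4, 9} half/half inverts to 6.25 < 6.5
  sq <- ls_utility_function(c(0, 4, 6.25, 9), c(0, 2, 2.5, 3))
  expect_equal(as.numeric(certainty_equivalent(sq, 2.5)), 6.25,
               tolerance = 1e-8)
  # flat function: lowest life satisfaction attaining the value
  flat <- ls_utility_function(c(0, 10), c(1, 1 + 1e-15))
  expect_lt(as.numeric(certainty_equivalent(flat, 1)), 1e-6)
  # out-of-range utilities clamp with a flag
  ce <- certainty_equivalent(lin_fn(), 25)
  expect_equal(as.numeric(ce), 10)
  expect_true(attr(ce, "clamped"))
})

test_that("RLS equals the mean for linear cohorts and is below it for concave", {
  d <- uk_dist()
  lins <- replicate(5, lin_fn(), simplify = FALSE)
  for (m in c("mean_utility", "median_participant", "median_curve")) {
    r <- rls(lins, d, method = m)
    expect_equal(r$rls, 7.65, tolerance = 1e-6)
    expect_equal(r$difference, 0, tolerance = 1e-6)
  }
  concs <- replicate(5, conc_fn(), simplify = FALSE)
  for (m in c("mean_utility", "median_participant", "median_curve")) {
    expect_lt(rls(concs, d, method = m)$rls, 7.65)
  }
  # degenerate distribution: RLS is its support point under every method
  # (normalisation against the non-degenerate reference)
  degen <- binned_ls_distribution(c(0, 0, 1, 0))
  for (m in c("mean_utility", "median_participant")) {
    expect_equal(rls(concs, degen, method = m, ref = d)$rls, 7.5,
                 tolerance = 1e-6)
  }
  expect_error(rls(list(), d), "empty cohort")
})

test_that("mean-utility RLS is invariant to per-participant affine transforms", {
  d <- uk_dist()
  fns <- list(conc_fn(), lin_fn(),
              ls_utility_function(c(2, 6, 10), c(0, 0.8, 1)))
  r0 <- rls(fns, d, method = "mean_utility")$rls
  aff <- mapply(function(fn, a, b) ls_utility_function(fn$ls,
                                                       a * fn$utility + b),
                fns, c(2, 0.5, 7), c(-1, 3, 0.2), SIMPLIFY = FALSE)
  expect_equal(rls(aff, d, method = "mean_utility")$rls, r0,
               tolerance = 1e-6)
})

test_that("median-participant RLS needs no normalisation: affine invariance", {
  # each participant's certainty equivalent is untouched by a positive affine
  # transform of their own utilities, so the median of them is too (expected
  # utility is cardinal, so this is the strongest transform class preserved)
  d <- uk_dist()
  fns <- list(conc_fn(), lin_fn(),
              ls_utility_function(c(2, 6, 10), c(0, 0.8, 1)))
  r0 <- rls(fns, d, method = "median_participant")$rls
  set.seed(14)
  for (rep in 1:5) {
    warped <- mapply(function(fn, a, b) {
      ls_utility_function(fn$ls, a * fn$utility + b)
    }, fns, runif(3, 0.2, 5), runif(3, -3, 3), SIMPLIFY = FALSE)
    expect_equal(rls(warped, d, method = "median_participant")$rls, r0,
                 tolerance = 1e-6)
  }
})

test_that("more concave societal curves give lower societal RLS", {
  pop <- det_population(societal_multiplier_meanlog = log(2.8),
                        societal_multiplier_sdlog = 0.3)
  sim <- simulate_cohort(60, pop, seed = 17)
  el <- elicit_cohort(sim$respondents)
  tab <- rls_table(el, sim$respondents, uk_dist())
  for (m in unique(tab$method)) {
    expect_lte(tab$rls[tab$context == "societal" & tab$method == m],
               tab$rls[tab$context == "personal" & tab$method == m])
  }
  expect_true(all(tab$rls <= tab$mean_ls + 1e-9))
})
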