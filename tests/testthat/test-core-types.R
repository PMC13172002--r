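test_that("probability grid round-trips through exact fraction labels", {
  g <- probability_grid()
  expect_length(g, 8L)
  expect_true(all(diff(g) < 0))
  expect_identical(parse_probability(names(g)), unname(g))
  expect_identical(format_probability(unname(g)), names(g))
  expect_error(parse_probability("1/3"), "non-grid")
  expect_error(format_probability(0.3), "not on the grid")
})

test_that("state ranks order death below the living states", {
  expect_identical(state_levels()[1], "F")
  expect_identical(state_rank(c("F", "E", "A")), c(1L, 2L, 6L))
  expect_error(state_rank("Z"), "unknown state")
})

test_that("gamble specs enforce rank order and block adjacency", {
  g <- gamble_spec("E", "D", "F", "personal", "adjacent_personal")
  expect_s3_class(g, "sg_gamble")
  expect_error(gamble_spec("E", "F", "D", "personal", "adjacent_personal"),
               "rank")
  expect_error(gamble_spec("D", "A", "F", "personal", "adjacent_personal"),
               "one step")
  expect_error(gamble_spec("D", "C", "E", "personal", "nonadjacent_personal"),
               "2-3 steps")
  expect_error(gamble_spec("E", "D", "F", "societal", "adjacent_personal"),
               "disagree")
  # nonadjacent arms are capped at three rank steps
  expect_silent(gamble_spec("D", "A", "F", "personal", "nonadjacent_personal"))
  expect_error(gamble_spec("E", "A", "F", "personal", "nonadjacent_personal"),
               "2-3 steps")
})

test_that("nonadjacent triple enumeration matches its definition", {
  tr <- nonadjacent_triples()
  for (i in seq_len(nrow(tr))) {
    up <- state_rank(tr$win[i]) - state_rank(tr$baseline[i])
    down <- state_rank(tr$baseline[i]) - state_rank(tr$lose[i])
    expect_true(up >= 1 && up <= 3 && down >= 1 && down <= 3)
    expect_false(up == 1 && down == 1)
  }
})

test_that("ladder stopping rules are enforced", {
  g <- gamble_spec("E", "D", "F", "personal", "adjacent_personal")
  expect_false(ladder_response(g, c("reject", "accept"))$undecidable)
  expect_false(ladder_response(g, rep("reject", 8))$undecidable)
  # accept must terminate; decisions cannot continue past undecidability
  expect_error(ladder_response(g, c("accept", "reject")), "ends the ladder")
  expect_error(ladder_response(g, c("reject", "reject")), "ends without")
  expect_error(
    ladder_response(g, c("cant_choose", "cant_choose", "reject")),
    "undecidable")
  # two consecutive cant_choose, or one at the lowest odds, are undecidable
  expect_true(ladder_response(g, c("cant_choose", "cant_choose"))$undecidable)
  expect_true(
    ladder_response(g, c("reject", "cant_choose", "cant_choose"))$undecidable)
  expect_true(
    ladder_response(g, c(rep("reject", 7), "cant_choose"))$undecidable)
  # a lone cant_choose mid-ladder is fine when followed by a decision
  l <- ladder_response(g, c("cant_choose", "accept"))
  expect_false(l$undecidable)
})

test_that("respondent invariants: rating order flag and block composition", {
  ladders <- lapply(c(adjacent_gambles("personal"), adjacent_gambles("societal"),
                      personal_design()[5:8]),
                    function(g) ladder_response(g, c("reject", "accept")))
  r <- respondent("p1", "gambles_first", ladders = ladders,
                  vignette_ratings = c(A = 10, B = 8, C = 6, D = 4, E = 2))
  expect_false(r$flags$order_violation)
  expect_equal(r$political_score, 15)
  r2 <- respondent("p2", "ls_first", ladders = ladders,
                   vignette_ratings = c(A = 10, B = 8, C = 9, D = 4, E = 2))
  expect_true(r2$flags$order_violation)
  expect_error(respondent("p3", ladders = ladders[1:11]), "12 ladders")
  expect_error(respondent("p4", ladders = ladders,
                          vignette_ratings = c(A = 10, B = 8, C = 6.5,
                                               D = 4, E = 2)),
               "integers")
})

test_that("respondent CSV writer and reader are mutually inverse", {
  sim <- simulate_cohort(3, det_population(cant_choose_rate = 0.15), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_respondents(sim$respondents, path)
  back <- read_respondents(path)
  expect_equal(back, sim$respondents)
  # undecidable ladders survive the trip
  und <- vapply(sim$respondents, function(r)
    any(vapply(r$ladders, function(l) l$undecidable, logical(1))), logical(1))
  expect_true(any(und))  # cant_choose rate high enough to produce some

  write_respondents(list(), path)
  expect_identical(read_respondents(path), list())
  expect_gt(length(readLines(path)), 0L)  # header survives
})

test_that("malformed respondent files are rejected with located diagnostics", {
  sim <- simulate_cohort(1, det_population(), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_respondents(sim$respondents, path)
  tab <- utils::read.csv(path, colClasses = c(p_loss = "character"))
  tab$p_loss[3] <- "1/3"
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(read_respondents(path), "non-grid")
  tab$p_loss <- NULL
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(read_respondents(path), "missing column")
})

test_that("binned distributions validate shares and bin cover", {
  d <- binned_ls_distribution(c(0.06, 0.10, 0.50, 0.34))
  expect_equal(sum(d$shares), 1)
  expect_equal(distribution_mean(d), 7.65)
  expect_error(binned_ls_distribution(c(0.05, 0.10, 0.50, 0.25)), "sum to 1")
  d2 <- binned_ls_distribution(c(0.05, 0.10, 0.50, 0.25), normalise = TRUE)
  expect_equal(sum(d2$shares), 1)
  expect_silent(binned_ls_distribution(c(0, 0, 1, 0)))
  expect_error(binned_ls_distribution(c(-0.1, 0.2, 0.5, 0.4)),
               "non-negative")
})

test_that("distribution CSV reader enforces the bin set", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_distribution(binned_ls_distribution(c(0.06, 0.10, 0.50, 0.34)), path)
  d <- read_distribution(path)
  expect_equal(d$shares, c(0.06, 0.10, 0.50, 0.34))
  expect_equal(d$representative_ls, c(2, 5.5, 7.5, 9.5))
  bad <- data.frame(ls_range = c("0-4", "5-6", "7-8", "9+"),
                    share = c(0.06, 0.10, 0.50, 0.34))
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_distribution(path), "bins")
  shipped <- system.file("extdata", "uk_ls_distribution_synthetic.csv",
                         package = "lsutility")
  expect_equal(read_distribution(shipped)$shares, c(0.06, 0.10, 0.50, 0.34))
})
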