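test_that("median/IQR fit recovers lognormal parameters", {
  lp <- lognormal_params_from_median_iqr(8298, 6532, 10111)
  expect_equal(lp$meanlog, log(8298))
  expect_equal(lp$sdlog,
               (log(10111 / 8298) + log(8298 / 6532)) / (2 * qnorm(0.75)))
  expect_equal(lp$sdlog, 0.3239, tolerance = 1e-3)
  # degenerate point mass
  expect_equal(lognormal_params_from_median_iqr(5, 5, 5)$sdlog, 0)
  # symmetric log-quartiles: closed form ln(r)/z
  r <- 1.2
  expect_equal(lognormal_params_from_median_iqr(10, 10 / r, 10 * r)$sdlog,
               log(r) / qnorm(0.75))
  expect_error(lognormal_params_from_median_iqr(5, 6, 7), "q1 <= median")
  expect_error(lognormal_params_from_median_iqr(5, -1, 7), "positive")
})

test_that("generation is a pure function of the spec and its seed", {
  spec <- portfolio_spec(n_eus = 40, seed = 123)
  expect_identical(generate_portfolio(spec), generate_portfolio(spec))
  other <- generate_portfolio(portfolio_spec(n_eus = 40, seed = 124))
  expect_false(identical(generate_portfolio(spec)$survey_cost,
                         other$survey_cost))
  # caller RNG state is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_portfolio(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated portfolios honour their spec's structure", {
  spec <- portfolio_spec(n_eus = 400, split_district_prob = 0.2, seed = 9)
  p <- generate_portfolio(spec)
  expect_equal(nrow(p), 400)
  expect_true(all(p$population >= 50000 - 1 &
                    p$population <= 500000 + 1))
  # each district campaign carries exactly one MDA cost
  n_mda <- tapply(!is.na(p$mda_cost), p$district, sum)
  expect_true(all(n_mda == 1))
  expect_true(any(table(p$district) == 2))  # some split districts

  none <- generate_portfolio(portfolio_spec(n_eus = 50,
                                            continuation_prob = 0, seed = 3))
  expect_true(all(none$tf_category == "under5"))
  all_cont <- generate_portfolio(portfolio_spec(n_eus = 50,
                                                continuation_prob = 1,
                                                seed = 3))
  expect_true(all(tf_needs_mda(all_cont$tf_category)))
})

test_that("generated portfolios round-trip the delimited schema", {
  spec <- portfolio_spec(n_eus = 12, split_district_prob = 0.3, seed = 21)
  p <- generate_portfolio(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eu_table(p, path, header_comment = "synthetic portfolio")
  back <- read_eu_table(path)
  expect_equal(back$survey_cost, p$survey_cost, tolerance = 1e-8)
  expect_equal(as.character(back$tf_category), as.character(p$tf_category))
  expect_equal(summarize_portfolio(back)$saving,
               summarize_portfolio(p)$saving, tolerance = 1e-8)
})

test_that("large samples recover the spec's median, IQR and continuation rate", {
  n <- 2000
  spec <- portfolio_spec(n_eus = n, split_district_prob = 0, seed = 77)
  p <- generate_portfolio(spec)
  expect_lt(abs(median(p$survey_cost) - 8298) / 8298, 0.02)
  q <- quantile(p$survey_cost, c(0.25, 0.75))
  expect_lt(abs(q[[1]] - 6532) / 6532, 0.05)
  expect_lt(abs(q[[2]] - 10111) / 10111, 0.05)
  phat <- mean(tf_needs_mda(p$tf_category))
  se <- sqrt(0.32 * 0.68 / n)
  expect_lt(abs(phat - 0.32), 3 * se)
})

test_that("realised strategy-(a) cost matches its expectation identity", {
  # cost_a = surveys + continuation-selected MDA; with outcomes independent
  # of costs, the selected share converges to p times the MDA total
  n <- 4000
  p <- generate_portfolio(portfolio_spec(n_eus = n, split_district_prob = 0,
                                         seed = 31))
  cont <- tf_needs_mda(p$tf_category)
  realised <- sum(p$survey_cost) + sum(p$mda_cost[cont])
  expected <- sum(p$survey_cost) + 0.32 * sum(p$mda_cost)
  se <- sqrt(0.32 * 0.68 * sum(p$mda_cost^2))
  expect_lt(abs(realised - expected), 3 * se)
})

test_that("simulated cost difference crosses zero at the closed-form rate", {
  # single EU, fixed costs: the crossing is 1 - 8298/28957.6 = 0.7134
  spec <- portfolio_spec(n_eus = 1, population_range = c(1e5, 1e5),
                         survey_cost_median = 8298,
                         survey_cost_iqr = c(8298, 8298),
                         ucmda_noise_sd = 0, split_district_prob = 0,
                         seed = 11)
  sim <- simulate_breakeven(spec, seq(0.6, 0.82, 0.02), replicates = 1500)
  # surveys clearly pay at the low end of the grid, clearly not at the top
  expect_gt(sim$mean_diff[1], 0)
  expect_lt(sim$mean_diff[nrow(sim)], 0)
  eb <- empirical_breakeven(sim)
  target <- breakeven_rate(8298, 0.28 * 1.0342 * 1e5)
  expect_lt(abs(eb$estimate - target), 3 * eb$se)

  # continuation probability zero: difference is MDA minus survey cost
  sim0 <- simulate_breakeven(spec, c(0, 0.5), replicates = 5)
  expect_equal(sim0$mean_diff[1], 0.28 * 1.0342 * 1e5 - 8298)
  expect_error(empirical_breakeven(sim0[1, , drop = FALSE]), "sign change")
})

test_that("portfolio specs validate their fields", {
  expect_error(portfolio_spec(n_eus = 5, continuation_prob = 1.2, seed = 1),
               "\\[0, 1\\]")
  expect_error(portfolio_spec(n_eus = 5,
                              continuing_category_weights = c(0.5, 0.4, 0.2),
                              seed = 1),
               "sum to 1")
  expect_error(portfolio_spec(n_eus = 5, survey_cost_median = 100,
                              survey_cost_iqr = c(200, 300), seed = 1))
  expect_error(portfolio_spec(n_eus = 5), "seed")
})
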