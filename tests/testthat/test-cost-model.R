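test_that("inflation converts 2015 USD to 2017 USD at full precision", {
  expect_equal(as.numeric(inflate(money(0.28, 2015), 1.0342)), 0.289576)
  expect_equal(currency_year(inflate(money(0.28, 2015), 1.0342)), 2017L)
  expect_equal(as.numeric(inflate(money(0.20, 2015), 1.0342)), 0.20684)
  # identity factor leaves the value unchanged
  expect_equal(as.numeric(inflate(money(8298, 2015), 1.0)), 8298)
  expect_error(inflate(money(1, 2015), 0), "positive")
  expect_error(inflate(money(1, 2015), -2), "positive")
})

test_that("inflation is linear and invertible to machine precision", {
  for (x in c(0.13, 0.39, 8298, 101930.53)) {
    back <- inflate(inflate(money(x, 2015), 1.0342), 1 / 1.0342, to_year = 2015)
    expect_equal(as.numeric(back), x, tolerance = 1e-12)
  }
  expect_equal(as.numeric(inflate(money(3, 2015), 1.0342)),
               3 * as.numeric(inflate(money(1, 2015), 1.0342)))
})

test_that("amounts from different currency years refuse to combine", {
  a15 <- money(0.28, 2015)
  a17 <- money(8298, 2017)
  expect_error(a15 + a17, "inflate")
  expect_error(sum(a15, a17), "currency years")
  expect_silent(a17 + money(100, 2017))
  expect_equal(as.numeric(sum(money(2, 2017), money(3, 2017))), 5)
  expect_error(money(-1, 2017), "nonnegative")
})

test_that("per-EU MDA cost is unit cost times population", {
  expect_equal(mda_cost_per_eu(0.289576, 100000), 28957.6)
  expect_equal(mda_cost_per_eu(0.403338, 50000), 20166.9)
  expect_error(mda_cost_per_eu(0.28, 0), ">= 1")
  expect_error(mda_cost_per_eu(0, 1000), "positive")
})

test_that("strategy costs follow the decision inequality's two sides", {
  expect_equal(strategy_a_cost(8298, 0.32, 28957.6), 17564.432)
  expect_equal(strategy_a_cost(8298, 0, 1e9), 8298)
  expect_equal(strategy_a_cost(6532, 0.32, 17581.4), 12158.048)
  expect_error(strategy_a_cost(8298, 1.2, 100), "\\[0, 1\\]")
  expect_error(strategy_a_cost(8298, -0.1, 100), "\\[0, 1\\]")
  expect_equal(strategy_b_cost(67223.0), 67223.0)
  expect_error(strategy_b_cost(-1), "nonnegative")
})

test_that("break-even rate is one minus the survey/MDA cost ratio", {
  expect_equal(breakeven_rate(8298, 28957.6), 1 - 8298 / 28957.6)
  expect_gt(breakeven_rate(8298, 28957.6), 0.713)
  expect_lt(breakeven_rate(8298, 28957.6), 0.714)
  expect_equal(breakeven_rate(8298, 41368), 1 - 8298 / 41368)
  expect_equal(breakeven_rate(5000, 5000), 0)
  # survey dearer than a round of MDA: surveying never pays within the year
  expect_lt(breakeven_rate(30000, 20000), 0)
  expect_error(breakeven_rate(8298, 0), "positive")
})

test_that("evaluation pairs low with low and high with high", {
  ev <- evaluate_strategies(cost_parameters(
    ucmda = interval_estimate(0.28, 0.17, 0.35, kind = "CI95"),
    eu_population = 100000
  ))
  expect_equal(ev$cost_a$point, 8298 + 0.32 * (0.28 * 1.0342 * 1e5))
  expect_equal(ev$cost_a$low, 6532 + 0.32 * (0.17 * 1.0342 * 1e5))
  expect_equal(ev$cost_a$high, 10111 + 0.32 * (0.35 * 1.0342 * 1e5))
  expect_equal(ev$cost_b$point, 28957.6)
  expect_equal(ev$cost_b$low, 17581.4)
  expect_equal(ev$cost_b$high, 36197, tolerance = 1e-9)
  expect_equal(ev$breakeven_rate$point, 1 - 8298 / 28957.6)
  expect_equal(ev$breakeven_rate$low, 1 - 6532 / 17581.4)
  expect_equal(ev$breakeven_rate$high, 1 - 10111 / (0.35 * 1.0342 * 1e5))

  ev250 <- evaluate_strategies(cost_parameters(
    ucmda = interval_estimate(0.18, 0.11, 0.23, kind = "CI95"),
    eu_population = 250000
  ))
  expect_equal(ev250$cost_a$point, 23190.48)

  ev0 <- evaluate_strategies(cost_parameters(
    ucmda = interval_estimate(0.28, 0.17, 0.35, kind = "CI95"),
    continuation_rate = 0, eu_population = 100000
  ))
  expect_equal(c(ev0$cost_a$point, ev0$cost_a$low, ev0$cost_a$high),
               c(8298, 6532, 10111))
})

test_that("a 2017-basis unit cost is not inflated again", {
  ev <- evaluate_strategies(cost_parameters(
    ucmda = interval_estimate(0.289576),
    ucmda_currency_year = 2017L,
    eu_population = 100000
  ))
  expect_equal(ev$cost_b$point, 28957.6)
})

test_that("display flooring truncates toward zero, guarding fp noise", {
  expect_identical(display_floor(20166.9, "dollar"), 20166)
  expect_identical(display_floor(0.79941, "percent"), 79)
  expect_identical(display_floor(17564.0, "dollar"), 17564)
  expect_identical(display_floor(0.5885, "percent"), 58)
  # 0.35 * 1.0342 * 1e5 is exactly 36,197 in decimal but sits just below
  # it in binary; the guard must not let it truncate to 36,196
  expect_identical(display_floor(0.35 * 1.0342 * 1e5, "dollar"), 36197)
  expect_identical(round_half_up(101930.53), 101931)
  expect_identical(round_half_up(409720.59), 409721)
  expect_identical(round_half_up(20166.5), 20167)
})

test_that("cost ordering and break-even threshold are algebraically equivalent", {
  set.seed(402)
  n <- 2000
  survey <- runif(n, 100, 60000)
  mda <- runif(n, 100, 90000)
  p <- runif(n)
  a <- strategy_a_cost(survey, p, mda)
  b <- strategy_b_cost(mda)
  be <- breakeven_rate(survey, mda)
  expect_equal(a < b, p < be)
  expect_equal(a > b, p > be)
  # certain continuation makes surveying strictly dearer
  expect_true(all(strategy_a_cost(survey, 1, mda) > b))
  # break-even lies in (0,1) exactly when the survey costs less than MDA
  expect_equal(be > 0 & be < 1, survey < mda & survey > 0)
})

test_that("interval estimates enforce their ordering invariant", {
  expect_error(interval_estimate(5, 6, 7), "low <= point <= high")
  expect_error(interval_estimate(5, 4, 4.5), "low <= point <= high")
  iv <- interval_estimate(8298, 6532, 10111, kind = "IQR")
  expect_equal(iv$kind, "IQR")
})
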