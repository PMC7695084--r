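#' Per-EU cost of one round of MDA
#'
#' The cost of treating a whole evaluation unit once: the per-person unit
#' cost of mass drug administration (excluding antibiotics and distributor
#' salaries/per diems) times the EU population. Full precision is kept;
#' flooring happens only at display.
#'
#' @param ucmda_2017 Unit cost of MDA, USD per person per year, 2017 price
#'   basis. Positive.
#' @param population EU population in persons (>= 1). Vectorised.
#' @return Numeric, USD per EU per year.
#' @examples
#' mda_cost_per_eu(0.28 * 1.0342, 100000)  # 28957.6
#' @export
mda_cost_per_eu <- function(ucmda_2017, population) {
  if (any(!is.finite(ucmda_2017)) || any(ucmda_2017 <= 0)) {
    stop("`ucmda_2017` must be positive", call. = FALSE)
  }
  if (any(!is.finite(population)) || any(population < 1)) {
    stop("`population` must be >= 1 person", call. = FALSE)
  }
  ucmda_2017 * population
}

#' Cost of strategy (a): survey, then MDA only where indicated
#'
#' Expected per-EU cost of conducting an impact survey and continuing MDA
#' only where the TF prevalence in 1- to 9-year-olds remains >= 5%:
#' `survey_cost + continuation_rate * mda_cost`.
#'
#' @param survey_cost Per-EU impact survey cost, USD. Nonnegative.
#' @param continuation_rate Proportion of surveys mandating further MDA,
#'   in \[0, 1\].
#' @param mda_cost Cost of one EU-wide MDA round, USD. Nonnegative.
#' @return Numeric, USD per EU per year. Vectorised over all arguments.
#' @examples
#' strategy_a_cost(8298, 0.32, 28957.6)  # 17564.43
#' @export
strategy_a_cost <- function(survey_cost, continuation_rate, mda_cost) {
  if (any(!is.finite(continuation_rate)) ||
      any(continuation_rate < 0) || any(continuation_rate > 1)) {
    stop("`continuation_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (any(survey_cost < 0) || any(mda_cost < 0)) {
    stop("costs must be nonnegative", call. = FALSE)
  }
  survey_cost + continuation_rate * mda_cost
}

#' Cost of strategy (b): continue MDA without surveying
#'
#' Identity on the one-round MDA cost; kept as a named operation so both
#' strategies appear symmetrically in tables and logs.
#'
#' @param mda_cost Cost of one EU-wide MDA round, USD. Nonnegative.
#' @return `mda_cost`, unchanged.
#' @export
strategy_b_cost <- function(mda_cost) {
  if (any(mda_cost < 0)) stop("`mda_cost` must be nonnegative", call. = FALSE)
  mda_cost
}

#' Break-even MDA continuation rate
#'
#' The continuation rate at which the two strategies cost the same:
#' `1 - survey_cost / mda_cost`. Below it, surveying first is cheaper.
#' The value is negative when the survey costs more than a round of MDA
#' (surveying then never pays for itself within the year).
#'
#' @inheritParams strategy_a_cost
#' @return Numeric proportion in (-Inf, 1). Vectorised.
#' @examples
#' breakeven_rate(8298, 28957.6)  # 0.7135: the 71% threshold at N = 100,000
#' @export
breakeven_rate <- function(survey_cost, mda_cost) {
  if (any(!is.finite(mda_cost)) || any(mda_cost <= 0)) {
    stop("`mda_cost` must be positive", call. = FALSE)
  }
  1 - survey_cost / mda_cost
}

#' Model parameters for a single-EU strategy comparison
#'
#' Bundles the inputs of the strategy-cost inequality: the per-EU survey
#' cost (2017 USD, median with IQR), the per-person MDA unit cost (point
#' with 95% CI, usually 2015 USD), the observed continuation rate, the
#' 2015-to-2017 inflation factor, and the mean EU population.
#'
#' @param survey_cost An [interval_estimate()] in 2017 USD per EU, or a
#'   single number (degenerate interval).
#' @param ucmda An [interval_estimate()] in USD per person per year, or a
#'   single number.
#' @param ucmda_currency_year Price basis of `ucmda`; 2015 values are
#'   inflated by `inflation_factor` during evaluation, 2017 values are used
#'   as is.
#' @param continuation_rate Proportion in \[0, 1\]; the global 2017-2018
#'   Tropical Data rate 0.32 is the default.
#' @param inflation_factor 2015-to-2017 USD multiplier, default 1.0342.
#' @param eu_population Mean EU population, persons (>= 1).
#' @return A list of class `"cost_parameters"`.
#' @examples
#' cost_parameters(
#'   survey_cost = interval_estimate(8298, 6532, 10111, kind = "IQR"),
#'   ucmda = interval_estimate(0.28, 0.17, 0.35, kind = "CI95"),
#'   eu_population = 100000
#' )
#' @export
cost_parameters <- function(survey_cost = interval_estimate(8298, 6532, 10111,
                                                            kind = "IQR"),
                            ucmda,
                            ucmda_currency_year = 2015L,
                            continuation_rate = 0.32,
                            inflation_factor = 1.0342,
                            eu_population) {
  as_iv <- function(x, kind) {
    if (is_interval_estimate(x)) x else interval_estimate(x, kind = kind)
  }
  survey_cost <- as_iv(survey_cost, "IQR")
  ucmda <- as_iv(ucmda, "CI95")
  stopifnot(ucmda$low > 0)
  if (continuation_rate < 0 || continuation_rate > 1) {
    stop("`continuation_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (inflation_factor <= 0) {
    stop("`inflation_factor` must be positive", call. = FALSE)
  }
  if (eu_population < 1) stop("`eu_population` must be >= 1", call. = FALSE)
  structure(list(survey_cost = survey_cost,
                 ucmda = ucmda,
                 ucmda_currency_year = as.integer(ucmda_currency_year),
                 continuation_rate = continuation_rate,
                 inflation_factor = inflation_factor,
                 eu_population = eu_population),
            class = "cost_parameters")
}

#' Evaluate both strategies with paired bound propagation
#'
#' Computes per-EU costs of strategy (a) (survey then MDA where indicated)
#' and strategy (b) (MDA without surveying), and the break-even continuation
#' rate, each as point/low/high triplets. Bounds are paired like with like —
#' the low survey cost goes with the low MDA unit cost, high with high —
#' matching how the published scenario table combines its IQR and 95% CI.
#' The result's intervals are labelled `"range"` because an IQR and a CI are
#' being mixed; they are reproduced as printed, not reinterpreted.
#'
#' @param params A [cost_parameters()] object.
#' @return A list of class `"strategy_evaluation"` with
#'   [interval_estimate()] fields `cost_a`, `cost_b` (USD per EU per year,
#'   2017 basis) and `breakeven_rate` (proportion), plus `mda_cost` and the
#'   echoed `params`.
#' @examples
#' ev <- evaluate_strategies(cost_parameters(
#'   ucmda = interval_estimate(0.28, 0.17, 0.35, kind = "CI95"),
#'   eu_population = 100000
#' ))
#' ev$breakeven_rate$point  # 0.7135
#' @export
evaluate_strategies <- function(params) {
  stopifnot(inherits(params, "cost_parameters"))
  f <- if (params$ucmda_currency_year < 2017L) params$inflation_factor else 1
  ucmda17 <- map_interval(function(u) u * f, params$ucmda)
  mda <- map_interval(mda_cost_per_eu, ucmda17, params$eu_population)
  cost_a <- map_interval(strategy_a_cost, params$survey_cost,
                         params$continuation_rate, mda)
  cost_b <- map_interval(strategy_b_cost, mda)
  be <- map_interval(breakeven_rate, params$survey_cost, mda)
  structure(list(cost_a = cost_a, cost_b = cost_b, breakeven_rate = be,
                 mda_cost = mda, params = params),
            class = "strategy_evaluation")
}

#' @export
print.strategy_evaluation <- function(x, ...) {
  fmt <- function(iv, scale = 1, unit = "dollar") {
    sprintf("%s (%s-%s)",
            format(display_floor(iv$point, unit), big.mark = ","),
            format(display_floor(iv$low, unit), big.mark = ","),
            format(display_floor(iv$high, unit), big.mark = ","))
  }
  cat("Per-EU annual cost, 2017 USD (point and range):\n")
  cat("  strategy (a) survey then MDA where indicated:",
      fmt(x$cost_a), "\n")
  cat("  strategy (b) MDA without surveying:          ",
      fmt(x$cost_b), "\n")
  cat("  break-even continuation rate, %:             ",
      fmt(x$breakeven_rate, unit = "percent"), "\n")
  invisible(x)
}

#' Whole-dollar / whole-percent display values
#'
#' The published scenario table truncates toward zero rather than rounding:
#' 20,166.9 displays as 20,166 and a break-even rate of 0.79941 as 79%.
#' A guard of 1e-6 absorbs binary floating-point representation of decimal
#' inputs (e.g. 0.35 x 1.0342 x 100,000, exactly 36,197 in decimal) before
#' truncating. Use for display only; keep full precision in arithmetic.
#'
#' @param x Numeric (a proportion when `unit = "percent"`).
#' @param unit `"dollar"` truncates `x`; `"percent"` truncates `100 * x`.
#' @return Integer-valued numeric.
#' @examples
#' display_floor(20166.9, "dollar")   # 20166
#' display_floor(0.79941, "percent")  # 79
#' @export
display_floor <- function(x, unit = c("dollar", "percent")) {
  unit <- match.arg(unit)
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  if (unit == "percent") x <- 100 * x
  trunc(round(x, 6))
}

#' Half-up rounding to whole units
#'
#' Narrative figures (totals, savings, the 32% global continuation rate)
#' are conventionally rounded, unlike the truncated table cells; base R
#' `round()` rounds half to even, so this helper is explicit about half-up.
#'
#' @param x Numeric.
#' @return Integer-valued numeric.
#' @examples
#' round_half_up(101930.53)  # 101931
#' @export
round_half_up <- function(x) floor(x + 0.5)
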