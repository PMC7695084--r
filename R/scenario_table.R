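#' Strategy costs and break-even rates across EU population sizes
#'
#' Builds the scenario grid: for each mean EU population, the per-EU annual
#' cost of strategy (a) (impact survey then MDA where indicated) and
#' strategy (b) (MDA without surveying), and the continuation rate at which
#' the two equalise — point and paired low/high bounds (survey-cost IQR
#' paired with MDA-cost 95% CI).
#'
#' Display convention (`raw = FALSE`), reverse-engineered from the published
#' grid and reproducing it cell for cell: per-EU MDA costs are truncated to
#' whole dollars; strategy (a) is recomposed from the truncated MDA cost and
#' rounded half-up; break-even percentages are computed from the truncated
#' MDA cost and truncated to whole percent. With `raw = TRUE` every column
#' is full precision (break-even as a proportion), for onward computation.
#'
#' @param populations Strictly increasing EU populations, persons. Default:
#'   the six benchmark sizes.
#' @param survey_cost [interval_estimate()] of per-EU survey cost, 2017 USD.
#' @param ucmda_entries Data frame with columns `population`, `point`,
#'   `low`, `high`: per-person MDA unit costs (2015 USD) for at least every
#'   requested population. Default: the published constants
#'   [ucmda_printed_2015()].
#' @param continuation_rate Proportion of impact surveys mandating further
#'   MDA, default 0.32.
#' @param inflation_factor 2015-to-2017 USD multiplier, default 1.0342.
#' @param raw If `TRUE`, emit unrounded values.
#' @return Data frame with one row per population and columns
#'   `population`, `cost_a`, `cost_a_low`, `cost_a_high`,
#'   `cost_b`, `cost_b_low`, `cost_b_high`,
#'   `breakeven`, `breakeven_low`, `breakeven_high`
#'   (break-even in percent when floored, proportion when raw).
#' @examples
#' build_scenario_table()[2, ]  # N = 100,000: 17,564 / 28,957 / 71%
#' @export
build_scenario_table <- function(populations = ucmda_printed_2015()$population,
                                 survey_cost = interval_estimate(
                                   8298, 6532, 10111, kind = "IQR"),
                                 ucmda_entries = ucmda_printed_2015(),
                                 continuation_rate = 0.32,
                                 inflation_factor = 1.0342,
                                 raw = FALSE) {
  if (is.unsorted(populations, strictly = TRUE)) {
    stop("`populations` must be strictly increasing", call. = FALSE)
  }
  missing_n <- setdiff(populations, ucmda_entries$population)
  if (length(missing_n)) {
    stop("no ucMDA entry for population(s): ",
         paste(format(missing_n, big.mark = ","), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(populations, function(n) {
    e <- ucmda_entries[ucmda_entries$population == n, ]
    ev <- evaluate_strategies(cost_parameters(
      survey_cost = survey_cost,
      ucmda = interval_estimate(e$point, e$low, e$high, kind = "CI95"),
      ucmda_currency_year = 2015L,
      continuation_rate = continuation_rate,
      inflation_factor = inflation_factor,
      eu_population = n
    ))
    if (raw) {
      data.frame(population = n,
                 cost_a = ev$cost_a$point, cost_a_low = ev$cost_a$low,
                 cost_a_high = ev$cost_a$high,
                 cost_b = ev$cost_b$point, cost_b_low = ev$cost_b$low,
                 cost_b_high = ev$cost_b$high,
                 breakeven = ev$breakeven_rate$point,
                 breakeven_low = ev$breakeven_rate$low,
                 breakeven_high = ev$breakeven_rate$high)
    } else {
      b <- vapply(c("point", "low", "high"),
                  function(l) display_floor(ev$cost_b[[l]], "dollar"),
                  numeric(1))
      s <- c(survey_cost$point, survey_cost$low, survey_cost$high)
      a <- round_half_up(s + continuation_rate * b)
      be <- vapply(seq_along(b),
                   function(i) display_floor(breakeven_rate(s[i], b[i]),
                                             "percent"),
                   numeric(1))
      data.frame(population = n,
                 cost_a = a[1], cost_a_low = a[2], cost_a_high = a[3],
                 cost_b = b[[1]], cost_b_low = b[[2]], cost_b_high = b[[3]],
                 breakeven = be[1], breakeven_low = be[2],
                 breakeven_high = be[3])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
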