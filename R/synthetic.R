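#' Lognormal parameters from a median and interquartile range
#'
#' Cost data are reported as a median with an IQR; for simulation we need a
#' full distribution. A lognormal is fitted with location `ln(median)` and
#' scale from the average of the two one-sided quartile fits:
#' `[ln(q3/median) + ln(median/q1)] / (2 * z_0.75)` with
#' `z_0.75 = qnorm(0.75)`. Exact when the data are lognormal with symmetric
#' log-quartiles; otherwise a documented stand-in (the source reports no
#' distributional family).
#'
#' @param median,q1,q3 Positive reals with `q1 <= median <= q3`.
#' @return List with `meanlog` and `sdlog` as used by [stats::rlnorm()].
#' @examples
#' lognormal_params_from_median_iqr(8298, 6532, 10111)
#' @export
lognormal_params_from_median_iqr <- function(median, q1, q3) {
  if (!(is.finite(median) && is.finite(q1) && is.finite(q3)) || q1 <= 0) {
    stop("quantiles must be positive finite numbers", call. = FALSE)
  }
  if (!(q1 <= median && median <= q3)) {
    stop("need q1 <= median <= q3", call. = FALSE)
  }
  list(meanlog = log(median),
       sdlog = (log(q3 / median) + log(median / q1)) /
         (2 * stats::qnorm(0.75)))
}

#' Specification of a synthetic EU survey portfolio
#'
#' Describes the statistical structure the cost analysis assumes, so every
#' downstream stage can be exercised on generated data: EU populations
#' log-uniform over the plausible range, per-EU survey costs lognormal
#' around the published median/IQR, district MDA unit costs following the
#' population power law with multiplicative lognormal noise, and TF
#' outcomes Bernoulli with the continuation probability.
#'
#' @param n_eus Number of evaluation units to generate.
#' @param population_range Min and max EU population, persons. Default
#'   50,000-500,000, the span of the published scenario grid.
#' @param survey_cost_median,survey_cost_iqr Per-EU survey cost summary in
#'   2017 USD; defaults $8,298 and ($6,532, $10,111).
#' @param ucmda_model A [unit_cost_model()]. The default is the published
#'   anchor ($0.28 at N = 100,000, elasticity -0.5) converted to the 2017
#'   price basis (x 1.0342) so generated MDA costs share the currency year
#'   of the generated survey costs.
#' @param ucmda_noise_sd SD of lognormal noise on the district unit cost,
#'   log scale. Default 0.18, matching the spread of the published 95% CI
#'   at N = 100,000 (`log(0.35/0.17)/(2 * 1.96)`).
#' @param continuation_prob Probability an EU's impact survey returns
#'   TF >= 5%. Default 0.32, the 2017-2018 global rate.
#' @param continuing_category_weights Probabilities over the continuing
#'   categories (`cat5to9`, `cat10to29`, `cat30plus`); must sum to 1.
#'   Default (0.6, 0.3, 0.1): most continuing surveys land just above the
#'   5% threshold.
#' @param split_district_prob Probability a district is surveyed as two
#'   EUs sharing one MDA campaign. Default 0.1 (2 of 18 campaigns in the
#'   Tanzania portfolio).
#' @param seed Integer seed; all generation is reproducible from it.
#' @return A list of class `"portfolio_spec"`.
#' @export
portfolio_spec <- function(n_eus,
                           population_range = c(50000, 500000),
                           survey_cost_median = 8298,
                           survey_cost_iqr = c(6532, 10111),
                           ucmda_model = unit_cost_model(
                             reference_ucmda = 0.28 * 1.0342,
                             currency_year = 2017L),
                           ucmda_noise_sd = 0.18,
                           continuation_prob = 0.32,
                           continuing_category_weights =
                             c(cat5to9 = 0.6, cat10to29 = 0.3,
                               cat30plus = 0.1),
                           split_district_prob = 0.1,
                           seed) {
  stopifnot(n_eus >= 1,
            length(population_range) == 2,
            population_range[1] >= 1,
            population_range[1] <= population_range[2],
            survey_cost_iqr[1] <= survey_cost_median,
            survey_cost_median <= survey_cost_iqr[2],
            inherits(ucmda_model, "unit_cost_model"),
            ucmda_noise_sd >= 0,
            length(continuing_category_weights) == 3)
  if (continuation_prob < 0 || continuation_prob > 1 ||
      split_district_prob < 0 || split_district_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(continuing_category_weights) - 1) > 1e-8) {
    stop("`continuing_category_weights` must sum to 1", call. = FALSE)
  }
  if (missing(seed) || length(seed) != 1 || is.na(seed)) {
    stop("an integer `seed` is required", call. = FALSE)
  }
  structure(list(n_eus = as.integer(n_eus),
                 population_range = population_range,
                 survey_cost_median = survey_cost_median,
                 survey_cost_iqr = survey_cost_iqr,
                 ucmda_model = ucmda_model,
                 ucmda_noise_sd = ucmda_noise_sd,
                 continuation_prob = continuation_prob,
                 continuing_category_weights = continuing_category_weights,
                 split_district_prob = split_district_prob,
                 seed = as.integer(seed)),
            class = "portfolio_spec")
}

# run code with a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# draw categories for EUs: under5 unless continuing, then by the weights
draw_categories <- function(n, p, weights) {
  cont <- stats::runif(n) < p
  cats <- rep("under5", n)
  if (any(cont)) {
    cats[cont] <- sample(c("cat5to9", "cat10to29", "cat30plus"),
                         sum(cont), replace = TRUE, prob = weights)
  }
  tf_category(cats)
}

# generation body; consumes the current RNG stream (no seeding here)
generate_portfolio_impl <- function(spec) {
  lp <- lognormal_params_from_median_iqr(spec$survey_cost_median,
                                         spec$survey_cost_iqr[1],
                                         spec$survey_cost_iqr[2])
  lo <- log(spec$population_range[1])
  hi <- log(spec$population_range[2])
  if (spec$split_district_prob == 0) {
    n <- spec$n_eus
    pop <- round(exp(stats::runif(n, lo, hi)))
    survey <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
    noise <- stats::rlnorm(n, 0, spec$ucmda_noise_sd)
    mda <- ucmda_at(spec$ucmda_model, pop) * noise * pop
    cats <- draw_categories(n, spec$continuation_prob,
                            spec$continuing_category_weights)
    ids <- sprintf("D%03d", seq_len(n))
    # bypass data.frame() validation: this constructor runs in tight
    # simulation loops and the columns are equal-length by construction
    return(structure(list(district = ids, eu = ids, year = rep(2017L, n),
                          survey_cost = survey, population = pop,
                          mda_cost = mda, tf_category = cats),
                     class = "data.frame", row.names = seq_len(n)))
  }
  rows <- vector("list", spec$n_eus)
  eus <- 0L
  d <- 0L
  while (eus < spec$n_eus) {
    d <- d + 1L
    split <- spec$n_eus - eus >= 2L &&
      stats::runif(1) < spec$split_district_prob
    k <- if (split) 2L else 1L
    pop <- round(exp(stats::runif(k, lo, hi)))
    survey <- stats::rlnorm(k, lp$meanlog, lp$sdlog)
    dpop <- sum(pop)
    uc <- ucmda_at(spec$ucmda_model, dpop) *
      stats::rlnorm(1, 0, spec$ucmda_noise_sd)
    cats <- draw_categories(k, spec$continuation_prob,
                            spec$continuing_category_weights)
    name <- sprintf("D%03d", d)
    rows[[d]] <- data.frame(
      district = name,
      eu = if (split) paste(name, c("south", "north")) else name,
      year = 2017L,
      survey_cost = survey,
      population = pop,
      mda_cost = c(uc * dpop, rep(NA_real_, k - 1L)),
      tf_category = cats,
      stringsAsFactors = FALSE)
    eus <- eus + k
  }
  out <- do.call(rbind, rows[seq_len(d)])
  rownames(out) <- NULL
  out
}

#' Generate a synthetic EU survey portfolio
#'
#' Draws a portfolio of evaluation units with the structure described by
#' the [portfolio_spec()]: log-uniform EU populations, lognormal survey
#' costs, power-law district MDA costs with multiplicative noise, Bernoulli
#' TF outcomes. Output uses the same schema as [read_eu_table()], so
#' generated portfolios flow through [summarize_portfolio()] and friends
#' unchanged; [write_eu_table()] serialises them to the delimited format.
#'
#' Generation is a pure function of the spec: the same spec (including its
#' seed) always yields the identical portfolio, and the caller's RNG state
#' is left untouched.
#'
#' @param spec A [portfolio_spec()].
#' @return Data frame of EU records (see [read_eu_table()]).
#' @examples
#' p <- generate_portfolio(portfolio_spec(n_eus = 5, seed = 42))
#' summarize_portfolio(p)
#' @export
generate_portfolio <- function(spec) {
  stopifnot(inherits(spec, "portfolio_spec"))
  with_seed(spec$seed, generate_portfolio_impl(spec))
}

#' Write EU records in the delimited survey-table schema
#'
#' @param records EU records ([read_eu_table()] schema).
#' @param path Output file path.
#' @param header_comment Optional character vector written as `#` comment
#'   lines above the header (provenance: package version, seed,
#'   parameters).
#' @return `path`, invisibly.
#' @export
write_eu_table <- function(records, path, header_comment = NULL) {
  tokens <- c(under5 = "<5", cat5to9 = "5-9.9", cat10to29 = "10-29.9",
              cat30plus = ">=30")
  out <- data.frame(district = records$district,
                    eu = records$eu,
                    year = records$year,
                    survey_cost_usd = records$survey_cost,
                    population = records$population,
                    mda_cost_usd = records$mda_cost,
                    tf_category = unname(tokens[as.character(records$tf_category)]))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# realized strategy-(b) minus strategy-(a) cost of one portfolio
strategy_cost_difference <- function(records) {
  if (!anyNA(records$mda_cost) && !anyDuplicated(records$district)) {
    # every EU is its own campaign
    return(sum(records$mda_cost * !tf_needs_mda(records$tf_category)) -
             sum(records$survey_cost))
  }
  key <- paste(records$district, records$year)
  cont <- tapply(tf_needs_mda(records$tf_category), key, any)
  mda <- tapply(records$mda_cost, key, sum, na.rm = TRUE)
  sum(mda) - (sum(records$survey_cost) + sum(mda[cont]))
}

#' Empirical break-even by portfolio simulation
#'
#' Sweeps the continuation probability over a grid; at each value draws
#' `replicates` portfolios and records the mean and standard error of the
#' realised cost difference (strategy b minus strategy a). The difference
#' decreases in the continuation probability, and its zero crossing is the
#' empirical break-even rate, validating the closed-form
#' `1 - Csurvey / (ucMDA x N)` by simulation. Use [empirical_breakeven()]
#' to interpolate the crossing and its Monte-Carlo standard error.
#'
#' @param spec A [portfolio_spec()]; its `continuation_prob` is overridden
#'   by each grid value in turn. The spec's seed makes the whole sweep
#'   reproducible.
#' @param continuation_grid Increasing grid of continuation probabilities.
#' @param replicates Portfolios drawn per grid value (>= 1).
#' @return Data frame with columns `continuation_prob`, `mean_diff`,
#'   `se_diff` (USD).
#' @examples
#' spec <- portfolio_spec(n_eus = 1, ucmda_noise_sd = 0, seed = 7)
#' sim <- simulate_breakeven(spec, seq(0.5, 0.9, 0.1), replicates = 200)
#' empirical_breakeven(sim)$estimate
#' @export
simulate_breakeven <- function(spec,
                               continuation_grid = seq(0, 1, by = 0.05),
                               replicates = 100) {
  stopifnot(inherits(spec, "portfolio_spec"), replicates >= 1)
  if (is.unsorted(continuation_grid, strictly = TRUE)) {
    stop("`continuation_grid` must be strictly increasing", call. = FALSE)
  }
  with_seed(spec$seed, {
    rows <- lapply(continuation_grid, function(p) {
      sp <- spec
      sp$continuation_prob <- p
      diffs <- vapply(seq_len(replicates), function(i) {
        strategy_cost_difference(generate_portfolio_impl(sp))
      }, numeric(1))
      data.frame(continuation_prob = p,
                 mean_diff = mean(diffs),
                 se_diff = stats::sd(diffs) / sqrt(replicates))
    })
    do.call(rbind, rows)
  })
}

#' Interpolated zero crossing of a break-even sweep
#'
#' Locates the grid interval where the mean cost difference changes sign
#' and linearly interpolates the crossing. The Monte-Carlo standard error
#' of the crossing is the pooled standard error of the bracketing means
#' divided by the local slope.
#'
#' @param sim Output of [simulate_breakeven()].
#' @return List with `estimate`, `se`, and the bracketing grid values
#'   `lower`, `upper`.
#' @export
empirical_breakeven <- function(sim) {
  d <- sim$mean_diff
  i <- which(d[-length(d)] >= 0 & d[-1] < 0)
  if (length(i) == 0) {
    stop("no sign change of the mean cost difference within the grid",
         call. = FALSE)
  }
  i <- i[1]
  p1 <- sim$continuation_prob[i]
  p2 <- sim$continuation_prob[i + 1]
  d1 <- d[i]
  d2 <- d[i + 1]
  slope <- (d2 - d1) / (p2 - p1)
  est <- p1 - d1 / slope
  se_d <- sqrt(mean(c(sim$se_diff[i]^2, sim$se_diff[i + 1]^2)))
  list(estimate = est, se = se_d / abs(slope), lower = p1, upper = p2)
}
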