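#' TF prevalence categories and the MDA rounds they trigger
#'
#' Impact survey results are binned on TF prevalence in 1- to 9-year-olds:
#' below 5% MDA stops; 5-9.9% triggers one more EU-wide round; 10-29.9%
#' three annual rounds; 30% and above five annual rounds. The categories
#' partition \[0, 100\]% and are written in input tables with the tokens
#' `"<5"`, `"5-9.9"`, `"10-29.9"`, `">=30"`.
#'
#' @param token Character vector of category tokens (or already-parsed
#'   labels `under5`, `cat5to9`, `cat10to29`, `cat30plus`).
#' @return `tf_category()`: a factor with levels
#'   `under5 < cat5to9 < cat10to29 < cat30plus`.
#' @examples
#' tf_category(c("<5", "10-29.9"))
#' mda_rounds_indicated(tf_category(">=30"))  # 5
#' @export
tf_category <- function(token) {
  labels <- c("<5" = "under5", "5-9.9" = "cat5to9",
              "10-29.9" = "cat10to29", ">=30" = "cat30plus")
  token <- trimws(as.character(token))
  parsed <- ifelse(token %in% labels, token, labels[token])
  if (any(is.na(parsed) | parsed == "")) {
    stop("unrecognised TF category token(s): ",
         paste(unique(token[is.na(parsed) | parsed == ""]), collapse = ", "),
         "; expected <5, 5-9.9, 10-29.9 or >=30", call. = FALSE)
  }
  factor(parsed, levels = unname(labels), ordered = TRUE)
}

#' @rdname tf_category
#' @param category A factor from [tf_category()].
#' @return `mda_rounds_indicated()`: integer rounds (0, 1, 3 or 5).
#' @export
mda_rounds_indicated <- function(category) {
  rounds <- c(under5 = 0L, cat5to9 = 1L, cat10to29 = 3L, cat30plus = 5L)
  unname(rounds[as.character(category)])
}

#' @rdname tf_category
#' @return `tf_needs_mda()`: logical, `TRUE` for every category except
#'   `under5`.
#' @export
tf_needs_mda <- function(category) {
  as.character(category) != "under5"
}

#' Path to the packaged Tanzania 2017-2018 impact survey table
#'
#' The 20 evaluation units surveyed by the United Republic of Tanzania's
#' trachoma elimination programme in 2017-2018, with per-EU survey costs,
#' populations, one-round MDA costs (one per district campaign; blank on
#' the second row of districts surveyed as two EUs) and the TF prevalence
#' category each survey returned. Values transcribed from the published
#' programme table.
#'
#' @return File path of the tab-separated fixture.
#' @export
tanzania_eu_path <- function() {
  system.file("extdata", "tanzania_eus_2017_2018.tsv",
              package = "trachomacost", mustWork = TRUE)
}

#' Read and validate a per-EU impact survey table
#'
#' Expects a delimited file with header columns `district`, `eu`, `year`,
#' `survey_cost_usd`, `population`, `mda_cost_usd`, `tf_category`.
#' `mda_cost_usd` is the cost of one district-wide MDA round and may be
#' blank on the extra rows of districts split into two EUs for survey
#' purposes; within each district campaign (district x survey year) exactly
#' one row must carry it.
#'
#' @param path File path; default the packaged Tanzania table.
#' @param sep Field separator, default tab.
#' @return Data frame of validated EU records with columns `district`,
#'   `eu`, `year`, `survey_cost`, `population`, `mda_cost` (NA on secondary
#'   split rows), `tf_category` (factor).
#' @examples
#' eus <- read_eu_table()
#' nrow(eus)  # 20 surveys
#' @export
read_eu_table <- function(path = tanzania_eu_path(), sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = TRUE, comment.char = "#")
  need <- c("district", "eu", "year", "survey_cost_usd", "population",
            "mda_cost_usd", "tf_category")
  if (!all(need %in% names(raw))) {
    stop("EU table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) stop("EU table is empty", call. = FALSE)
  rec <- data.frame(
    district = as.character(raw$district),
    eu = as.character(raw$eu),
    year = as.integer(raw$year),
    survey_cost = as.numeric(raw$survey_cost_usd),
    population = as.numeric(raw$population),
    mda_cost = suppressWarnings(as.numeric(raw$mda_cost_usd)),
    tf_category = tf_category(raw$tf_category),
    stringsAsFactors = FALSE
  )
  if (any(is.na(rec$survey_cost)) || any(rec$survey_cost < 0)) {
    stop("survey costs must be nonnegative numbers", call. = FALSE)
  }
  if (any(is.na(rec$population)) || any(rec$population < 1)) {
    stop("populations must be >= 1", call. = FALSE)
  }
  campaign <- interaction(rec$district, rec$year, drop = TRUE)
  n_mda <- tapply(!is.na(rec$mda_cost), campaign, sum)
  if (any(n_mda > 1)) {
    stop("duplicate one-round MDA cost within district campaign(s): ",
         paste(names(n_mda)[n_mda > 1], collapse = ", "), call. = FALSE)
  }
  if (any(n_mda < 1)) {
    stop("missing one-round MDA cost for district campaign(s): ",
         paste(names(n_mda)[n_mda < 1], collapse = ", "), call. = FALSE)
  }
  rec
}

#' Does a district campaign resume MDA?
#'
#' MDA is delivered district-wide, so a district surveyed as several EUs
#' resumes its single campaign if ANY constituent EU returned TF >= 5%
#' (the conservative public-health reading).
#'
#' @param tf_categories [tf_category()] values of the district's EUs.
#' @return Single logical.
#' @examples
#' district_continues(tf_category(c("<5", "5-9.9")))  # TRUE
#' @export
district_continues <- function(tf_categories) {
  if (length(tf_categories) < 1) stop("no records", call. = FALSE)
  any(tf_needs_mda(tf_categories))
}

#' Per-district-campaign strategy costs and savings
#'
#' Collapses EU records to district campaigns (district x survey year) and
#' computes, for each: the realised strategy-(a) cost (surveys, plus the
#' one-round MDA cost if any constituent EU mandated continuation), the
#' counterfactual strategy-(b) cost (MDA without surveying), and the annual
#' saving (b) - (a).
#'
#' @param records Validated EU records from [read_eu_table()].
#' @return Data frame with one row per campaign: `district`, `year`,
#'   `n_eus`, `population`, `survey_cost`, `mda_cost`, `continues`,
#'   `cost_a`, `cost_b`, `saving`.
#' @export
portfolio_by_district <- function(records) {
  key <- interaction(records$district, records$year, drop = TRUE)
  groups <- split(records, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    cont <- district_continues(g$tf_category)
    if (cont && length(unique(tf_needs_mda(g$tf_category))) > 1) {
      message("split district ", g$district[1], " (", g$year[1],
              "): mixed TF outcomes; district-wide MDA resumed")
    }
    mda <- g$mda_cost[!is.na(g$mda_cost)]
    data.frame(district = g$district[1], year = g$year[1],
               n_eus = nrow(g), population = sum(g$population),
               survey_cost = sum(g$survey_cost), mda_cost = mda,
               continues = cont,
               cost_a = sum(g$survey_cost) + if (cont) mda else 0,
               cost_b = mda,
               saving = mda - (sum(g$survey_cost) + if (cont) mda else 0),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$year, out$district), ]
  rownames(out) <- NULL
  out
}

#' Portfolio totals for a set of surveyed EUs
#'
#' Totals over a survey portfolio: the realised cost of surveying
#' everywhere and treating only where indicated (strategy a), the
#' counterfactual cost of treating everywhere without surveying
#' (strategy b), the saving, and the EU-level continuation rate. Full
#' precision throughout; round only at display.
#'
#' @param records Validated EU records from [read_eu_table()].
#' @return A list of class `"portfolio_summary"`: `n_eus`, `n_continuing`,
#'   `continuation_rate`, `total_survey_cost`, `total_cost_a`,
#'   `total_cost_b`, `saving`, `total_population` (costs in USD).
#' @examples
#' summarize_portfolio(read_eu_table())
#' @export
summarize_portfolio <- function(records) {
  stopifnot(nrow(records) >= 1)
  dist <- portfolio_by_district(records)
  total_a <- sum(dist$cost_a)
  total_b <- sum(dist$cost_b)
  structure(list(
    n_eus = nrow(records),
    n_continuing = sum(tf_needs_mda(records$tf_category)),
    continuation_rate = mean(tf_needs_mda(records$tf_category)),
    total_survey_cost = sum(records$survey_cost),
    total_cost_a = total_a,
    total_cost_b = total_b,
    saving = total_b - total_a,
    total_population = sum(records$population)
  ), class = "portfolio_summary")
}

#' @export
print.portfolio_summary <- function(x, ...) {
  d <- function(v) format(round_half_up(v), big.mark = ",")
  cat(sprintf("Portfolio of %d EUs (%s people surveyed)\n",
              x$n_eus, format(x$total_population, big.mark = ",")))
  cat(sprintf("  continuation rate: %d/%d (%s%%)\n", x$n_continuing, x$n_eus,
              format(round_half_up(100 * x$continuation_rate))))
  cat("  strategy (a) survey then MDA where indicated: $", d(x$total_cost_a),
      "\n", sep = "")
  cat("  strategy (b) MDA without surveying:           $", d(x$total_cost_b),
      "\n", sep = "")
  cat("  saving from surveying first:                  $", d(x$saving),
      sprintf(" (%s%%)\n", format(round_half_up(100 * x$saving /
                                                  x$total_cost_b))), sep = "")
  invisible(x)
}

#' People-equivalent of a saving
#'
#' Expresses a dollar saving as the number of people who could receive one
#' round of MDA at a given local per-person cost (whole persons, truncated).
#' The Tanzania 2017-2018 local MDA cost was $0.0981 per person.
#'
#' @param saving Saving in USD.
#' @param per_person_cost Local MDA cost, USD per person. Positive.
#' @return Whole number of persons.
#' @examples
#' people_equivalent(101930.53, 0.0981)  # > 1 million people
#' @export
people_equivalent <- function(saving, per_person_cost = 0.0981) {
  if (!is.finite(per_person_cost) || per_person_cost <= 0) {
    stop("`per_person_cost` must be positive", call. = FALSE)
  }
  floor(saving / per_person_cost)
}
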