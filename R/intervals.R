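#' Point estimate with a lower and upper bound
#'
#' A light container for the summary triplets used throughout the model:
#' a point value with a parenthetical range, as cost data are published. The survey cost carries an IQR,
#' the MDA unit cost a 95% CI; quantities derived by combining the two are
#' labelled `"range"` because the mixture is not a formal interval of either
#' kind.
#'
#' @param point,low,high Numerics with `low <= point <= high`.
#' @param kind One of `"IQR"`, `"CI95"`, `"range"`.
#' @return A list of class `"interval_estimate"` with elements
#'   `point`, `low`, `high`, `kind`.
#' @examples
#' interval_estimate(8298, 6532, 10111, kind = "IQR")
#' @export
interval_estimate <- function(point, low = point, high = point,
                              kind = c("range", "IQR", "CI95")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(point), is.numeric(low), is.numeric(high),
            length(point) == 1L, length(low) == 1L, length(high) == 1L)
  if (!(low <= point && point <= high)) {
    stop("interval requires low <= point <= high", call. = FALSE)
  }
  new_interval_estimate(point, low, high, kind)
}

# unvalidated constructor: derived triplets are paired scenarios (low input
# with low input), and with asymmetric inputs the "low" scenario of a
# derived quantity can land numerically above the "high" one
new_interval_estimate <- function(point, low, high, kind) {
  structure(list(point = point, low = low, high = high, kind = kind),
            class = "interval_estimate")
}

#' @rdname interval_estimate
#' @param x An object.
#' @export
is_interval_estimate <- function(x) inherits(x, "interval_estimate")

#' @export
print.interval_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s (%s: %s-%s)\n",
              format(x$point, digits = digits),
              x$kind,
              format(x$low, digits = digits),
              format(x$high, digits = digits)))
  invisible(x)
}

# apply f to each bound level, pairing like with like
map_interval <- function(f, ..., kind = "range") {
  ivs <- list(...)
  vals <- lapply(c("point", "low", "high"), function(lev) {
    do.call(f, lapply(ivs, function(iv) {
      if (is_interval_estimate(iv)) iv[[lev]] else iv
    }))
  })
  new_interval_estimate(vals[[1]], vals[[2]], vals[[3]], kind = kind)
}
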