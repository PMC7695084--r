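#' Dollar amounts tagged with a currency year
#'
#' Cost data in this model come in two price bases: MDA unit costs are
#' published in 2015 USD, survey costs in 2017 USD. To prevent silent mixing
#' of the two, monetary amounts carry a `currency_year` attribute and
#' arithmetic between amounts from different years is an error; convert with
#' [inflate()] first.
#'
#' @param value Numeric vector of nonnegative dollar amounts.
#' @param currency_year Integer year label of the price basis (e.g. 2015, 2017).
#' @return A numeric vector of class `"money"`.
#' @examples
#' money(8298, 2017)
#' inflate(money(0.28, 2015), 1.0342)
#' @export
money <- function(value, currency_year) {
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("`value` must be finite numeric", call. = FALSE)
  }
  if (any(value < 0)) {
    stop("monetary amounts must be nonnegative", call. = FALSE)
  }
  if (length(currency_year) != 1L || is.na(currency_year)) {
    stop("`currency_year` must be a single year", call. = FALSE)
  }
  structure(as.numeric(value),
            currency_year = as.integer(currency_year),
            class = "money")
}

#' @rdname money
#' @param x An object.
#' @export
is_money <- function(x) inherits(x, "money")

#' @rdname money
#' @export
currency_year <- function(x) {
  if (!is_money(x)) stop("not a money object", call. = FALSE)
  attr(x, "currency_year")
}

#' @export
print.money <- function(x, ...) {
  cat(sprintf("<money, %d USD>\n", currency_year(x)))
  print(unclass(structure(as.numeric(x), currency_year = NULL)))
  invisible(x)
}

#' @export
format.money <- function(x, ...) {
  paste0("$", formatC(as.numeric(x), format = "f", big.mark = ",", ...),
         " (", currency_year(x), " USD)")
}

check_same_year <- function(e1, e2) {
  if (is_money(e1) && is_money(e2) && currency_year(e1) != currency_year(e2)) {
    stop(sprintf("cannot combine amounts in %d USD and %d USD; inflate() first",
                 currency_year(e1), currency_year(e2)), call. = FALSE)
  }
}

#' @export
Ops.money <- function(e1, e2) {
  if (!missing(e2)) check_same_year(e1, e2)
  yr <- if (is_money(e1)) currency_year(e1) else currency_year(e2)
  out <- NextMethod()
  if (.Generic %in% c("+", "-", "*", "/") && is.numeric(out)) {
    # products/quotients of two money amounts are not money (units cancel)
    both <- !missing(e2) && is_money(e1) && is_money(e2)
    if (.Generic %in% c("+", "-") || !both) {
      return(money(out, yr))
    }
    attributes(out) <- NULL
  }
  out
}

#' @export
sum.money <- function(..., na.rm = FALSE) {
  amts <- list(...)
  yrs <- unique(vapply(amts, currency_year, integer(1)))
  if (length(yrs) > 1L) {
    stop("cannot sum amounts with different currency years", call. = FALSE)
  }
  money(sum(vapply(amts, function(a) sum(as.numeric(a), na.rm = na.rm),
                   numeric(1))), yrs)
}

#' Convert an amount to a later price basis
#'
#' Multiplies by an inflation factor and advances the currency-year label.
#' The packaged default converts 2015 USD to 2017 USD with the factor 1.0342
#' used throughout the model. Full precision is retained; no rounding.
#'
#' @param amount A [money()] amount.
#' @param factor Positive inflation multiplier. Default 1.0342 (2015 to 2017).
#' @param to_year Year label of the result. Default 2017.
#' @return A [money()] amount in `to_year` USD.
#' @examples
#' inflate(money(0.28, 2015), 1.0342)  # 0.289576, 2017 USD
#' @export
inflate <- function(amount, factor = 1.0342, to_year = 2017L) {
  if (!is_money(amount)) stop("`amount` must be a money object", call. = FALSE)
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("inflation `factor` must be a single positive number", call. = FALSE)
  }
  money(as.numeric(amount) * factor, to_year)
}
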