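# Money and exchange-rate handling. All cross-currency arithmetic in the
# package goes through an explicit ExchangeRateTable; amounts are never
# silently coerced between currencies.

currency_aliases <- c("R$" = "BRL", "EURO" = "EUR")

normalise_currency <- function(code) {
  code <- toupper(trimws(as.character(code)))
  hit <- match(code, names(currency_aliases))
  code[!is.na(hit)] <- currency_aliases[hit[!is.na(hit)]]
  code
}

#' Monetary amount tagged with a currency
#'
#' A `money` object is a numeric amount plus an ISO-4217-style currency
#' code. Addition, subtraction and comparison are only defined between two
#' amounts in the same currency; mixing currencies raises a classed
#' `vbp_currency_mismatch` error. Multiplication/division by a plain
#' number scales the amount. `"R$"` is accepted as an alias for `BRL`.
#'
#' @param amount numeric amount (no implicit rounding is applied).
#' @param currency currency code, e.g. `"EUR"`, `"GBP"`, `"BRL"`.
#' @return an object of class `money`.
#' @export
#' @examples
#' money(16000, "R$") # normalised to BRL
#' money(15702, "EUR") - money(7000, "EUR")
money <- function(amount, currency = "EUR") {
  if (!is.numeric(amount)) stop_domain("money amount must be numeric")
  currency <- normalise_currency(currency)
  if (length(currency) != 1L || is.na(currency) || !nzchar(currency))
    stop_domain("money requires a single non-empty currency code")
  structure(list(amount = as.numeric(amount), currency = currency),
            class = "money")
}

#' @export
format.money <- function(x, ...) {
  paste0(x$currency, " ", format(x$amount, big.mark = ",", trim = TRUE, ...))
}

#' @export
print.money <- function(x, ...) {
  cat("<money>", format(x), "\n")
  invisible(x)
}

check_same_currency <- function(a, b) {
  if (a$currency != b$currency) stop_currency_mismatch(a$currency, b$currency)
}

#' @export
Ops.money <- function(e1, e2) {
  op <- .Generic
  if (missing(e2)) { # unary +/-
    if (!op %in% c("+", "-")) stop_domain(sprintf("unary %s undefined for money", op))
    return(money(get(op)(e1$amount), e1$currency))
  }
  m1 <- inherits(e1, "money"); m2 <- inherits(e2, "money")
  if (op %in% c("+", "-")) {
    if (!(m1 && m2))
      stop_domain("money can only be added to or subtracted from money of the same currency")
    check_same_currency(e1, e2)
    money(get(op)(e1$amount, e2$amount), e1$currency)
  } else if (op %in% c("*", "/")) {
    if (m1 && m2) stop_domain(sprintf("%s undefined between two money amounts", op))
    if (m1) money(get(op)(e1$amount, e2), e1$currency)
    else if (op == "*") money(e1 * e2$amount, e2$currency)
    else stop_domain("cannot divide a scalar by money")
  } else if (op %in% c("==", "!=", "<", "<=", ">", ">=")) {
    if (!(m1 && m2)) stop_domain("money compares only with money")
    check_same_currency(e1, e2)
    get(op)(e1$amount, e2$amount)
  } else {
    stop_domain(sprintf("operation %s undefined for money", op))
  }
}

#' Exchange-rate table in the units-per-euro convention
#'
#' Rates are stored as foreign units per one euro (the convention
#' "1 EUR = 0.833 GBP" is entered as `GBP = 0.833`), so conversion *to*
#' euro is division by the rate. `EUR` must map to exactly 1 (it is added
#' if absent) and all rates must be strictly positive.
#'
#' @param rates named numeric vector or list, currency code -> units per EUR.
#' @param as_of free-text date or provenance tag for the rates.
#' @return an object of class `exchange_rate_table`.
#' @seealso [read_exchange_rates()], [to_eur()]
#' @export
#' @examples
#' exchange_rate_table(c(GBP = 0.833, BRL = 5.15))
exchange_rate_table <- function(rates, as_of = NA_character_) {
  rates <- unlist(rates)
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop_validation("exchange rates must be a named currency -> rate mapping")
  names(rates) <- normalise_currency(names(rates))
  if (!is.numeric(rates) || any(!is.finite(rates)) || any(rates <= 0))
    stop_validation("all exchange rates must be strictly positive finite numbers")
  if ("EUR" %in% names(rates)) {
    if (rates[["EUR"]] != 1)
      stop_validation("EUR must map to exactly 1 in a units-per-euro table")
  } else {
    rates <- c(EUR = 1, rates)
  }
  structure(list(rates = rates, as_of = as.character(as_of)),
            class = "exchange_rate_table")
}

#' @export
print.exchange_rate_table <- function(x, ...) {
  cat("<exchange_rate_table>", if (!is.na(x$as_of)) paste0("as of ", x$as_of), "\n")
  for (cc in names(x$rates)) cat(sprintf("  EUR 1.00 = %s %s\n", cc, format(x$rates[[cc]])))
  invisible(x)
}

#' Read an exchange-rate table from JSON
#'
#' Expects `{"as_of": "...", "rates": {"EUR": 1, "GBP": 0.833, ...}}` with
#' rates in the units-per-euro convention.
#'
#' @param path path to a JSON file.
#' @return an [exchange_rate_table()].
#' @export
read_exchange_rates <- function(path) {
  if (!file.exists(path))
    stop_validation(sprintf("rates file not found: %s", path))
  j <- jsonlite::fromJSON(path)
  if (is.null(j$rates)) stop_validation(sprintf("no 'rates' field in %s", path))
  exchange_rate_table(j$rates, as_of = if (is.null(j$as_of)) NA_character_ else j$as_of)
}

#' Convert a monetary amount to euro
#'
#' Divides the amount by the table's units-per-euro rate for its currency.
#' The result is rounded to `digits` decimal places (default 6); no other
#' rounding happens anywhere in the conversion chain.
#'
#' @param m a [money()] amount.
#' @param rates an [exchange_rate_table()].
#' @param digits decimal places kept after conversion.
#' @return a [money()] amount in EUR.
#' @export
#' @examples
#' rates <- exchange_rate_table(c(GBP = 0.833))
#' to_eur(money(10704, "GBP"), rates)
to_eur <- function(m, rates, digits = 6) {
  if (!inherits(m, "money")) stop_domain("to_eur expects a money object")
  if (!inherits(rates, "exchange_rate_table"))
    stop_domain("rates must be an exchange_rate_table")
  if (m$currency == "EUR") return(m)
  rate <- rates$rates[m$currency]
  if (is.na(rate))
    stop_vbp(sprintf("no exchange rate for currency %s", m$currency),
             "vbp_missing_rate", currency = m$currency)
  money(round(m$amount / unname(rate), digits), "EUR")
}
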