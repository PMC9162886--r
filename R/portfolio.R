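# Portfolio I/O and the end-to-end pricing pipeline: read device records,
# screen for usable cost-effectiveness data, convert to EUR, price at two
# thresholds, compare with real prices, and write results.

portfolio_required_cols <- c("device_id", "name", "real_price",
                             "real_price_currency", "has_cea")
portfolio_optional_cols <- c(
  description = "", comparator = "",
  gain = NA_real_, outcome_kind = NA_character_,
  surv1y_a = NA_real_, surv1y_b = NA_real_,
  cost_b = NA_real_, cost_b_currency = NA_character_,
  othercosts_a = NA_real_, othercosts_a_currency = NA_character_,
  time_horizon_months = NA_character_, source = "", source_kind = NA_character_,
  reported_vbp_eur = NA_real_)

accepted_source_kinds <- c("CEA_registry", "HTA_report")

#' Read a device portfolio from CSV or JSON
#'
#' A portfolio is one row per device: identity, real unit price with its
#' currency, a `has_cea` flag, and — for devices with usable
#' cost-effectiveness data — the pricing parameters (`gain`, `cost_b`,
#' `othercosts_a`, each cost with its currency, `source_kind`). Devices
#' whose CEA reports only one-year survival proportions may leave `gain`
#' empty and give `surv1y_a`/`surv1y_b` instead; the life-year gain is then
#' derived via [survival_gain_one_year()]. Files are UTF-8 with "." as the
#' decimal separator. A JSON file holding an array of record objects with
#' the same fields is accepted as an alternative to CSV.
#'
#' @param path path to a `.csv` or `.json` portfolio file.
#' @param rates optional [exchange_rate_table()]; when given, every
#'   currency used in the file is checked to be resolvable.
#' @return a `data.frame` of validated device records (invisibly warns and
#'   returns zero rows for an empty file). Malformed rows raise a
#'   validation error naming the rows and fields.
#' @export
read_portfolio <- function(path, rates = NULL) {
  if (!file.exists(path)) stop_validation(sprintf("portfolio file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0) df <- data.frame()
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  if (nrow(df) == 0) {
    warning("portfolio file is empty: ", path, call. = FALSE)
    df <- as.data.frame(c(setNames(rep(list(character(0)), length(portfolio_required_cols)),
                                   portfolio_required_cols),
                          lapply(portfolio_optional_cols, `[`, 0)),
                        stringsAsFactors = FALSE)
    return(df)
  }
  missing_cols <- setdiff(portfolio_required_cols, names(df))
  if (length(missing_cols))
    stop_validation(paste0("portfolio schema violation, missing columns: ",
                           paste(missing_cols, collapse = ", ")))
  for (col in names(portfolio_optional_cols))
    if (is.null(df[[col]])) df[[col]] <- portfolio_optional_cols[[col]]

  num_cols <- c("real_price", "gain", "surv1y_a", "surv1y_b",
                "cost_b", "othercosts_a", "reported_vbp_eur")
  for (col in num_cols) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$has_cea <- as.logical(df$has_cea)
  df$time_horizon_months <- as.character(df$time_horizon_months)
  for (col in c("real_price_currency", "cost_b_currency", "othercosts_a_currency")) {
    cur <- normalise_currency(df[[col]])
    cur[cur %in% c("", "NA")] <- NA_character_
    df[[col]] <- cur
  }

  # derive life-year gains from one-year survival proportions
  derive <- df$has_cea & is.na(df$gain) & !is.na(df$surv1y_a) & !is.na(df$surv1y_b)
  if (any(derive)) {
    df$gain[derive] <- mapply(survival_gain_one_year,
                              df$surv1y_a[derive], df$surv1y_b[derive])
    df$outcome_kind[derive] <- "life_year"
  }

  problems <- character(0)
  bad <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      problems <<- c(problems, paste0("row ", which(rows), ": ", what))
  }
  bad(is.na(df$real_price) | df$real_price <= 0, "real_price must be > 0")
  bad(is.na(df$real_price_currency), "real_price_currency missing")
  bad(is.na(df$has_cea), "has_cea must be TRUE/FALSE")
  cea <- !is.na(df$has_cea) & df$has_cea
  bad(cea & is.na(df$gain), "gain (or surv1y_a/surv1y_b) required when has_cea")
  bad(cea & (is.na(df$cost_b) | is.na(df$cost_b_currency)),
      "cost_b with currency required when has_cea")
  bad(cea & (is.na(df$othercosts_a) | is.na(df$othercosts_a_currency)),
      "othercosts_a with currency required when has_cea")
  bad(cea & !(df$outcome_kind %in% c("QALY", "life_year")),
      "outcome_kind must be QALY or life_year when has_cea")
  bad(cea & !(df$source_kind %in% accepted_source_kinds),
      paste0("source_kind must be one of ", paste(accepted_source_kinds, collapse = ", ")))
  if (!is.null(rates)) {
    used <- unique(stats::na.omit(c(df$cost_b_currency[cea], df$othercosts_a_currency[cea])))
    unresolvable <- setdiff(used, names(rates$rates))
    if (length(unresolvable))
      problems <- c(problems, paste0("currency without exchange rate: ",
                                     paste(unresolvable, collapse = ", ")))
  }
  if (length(problems))
    stop_validation(paste0("malformed portfolio rows in ", path, ":\n  ",
                           paste(problems, collapse = "\n  ")))
  df
}

record_to_cea_inputs <- function(rec) {
  cea_inputs(gain = rec$gain,
             cost_B = money(rec$cost_b, rec$cost_b_currency),
             othercosts_A = money(rec$othercosts_a, rec$othercosts_a_currency),
             outcome_kind = rec$outcome_kind,
             time_horizon_months = if (is.na(rec$time_horizon_months)) "lifetime"
                                   else rec$time_horizon_months,
             source = rec$source,
             source_kind = rec$source_kind)
}

#' Screen a portfolio for usable cost-effectiveness data
#'
#' A device is eligible when it carries CEA parameters whose source is one
#' of the two accepted kinds (a CEA registry entry or an HTA report).
#'
#' @param records portfolio `data.frame` from [read_portfolio()] or
#'   [generate_portfolio()].
#' @return a list with `eligible` (the eligible rows, input order
#'   preserved) and `summary`, a `screening_summary` with counts and the
#'   eligible percentage (both one-decimal and integer-rounded forms).
#' @export
screen_portfolio <- function(records) {
  ok <- !is.na(records$has_cea) & records$has_cea &
    records$source_kind %in% accepted_source_kinds
  n_total <- nrow(records)
  n_eligible <- sum(ok)
  pct <- if (n_total == 0) 0 else 100 * n_eligible / n_total
  summary <- structure(list(n_total = n_total, n_eligible = n_eligible,
                            pct_eligible = round_half_up(pct, 1),
                            pct_eligible_int = round_half_up(pct)),
                       class = "screening_summary")
  list(eligible = records[ok, , drop = FALSE], summary = summary)
}

#' @export
print.screening_summary <- function(x, ...) {
  cat(sprintf("Screening: %d of %d devices with usable CEA data (%d%%)\n",
              x$n_eligible, x$n_total, x$pct_eligible_int))
  invisible(x)
}

#' Run the full value-based pricing pipeline on a portfolio
#'
#' Screens the records, converts each eligible device's cost parameters to
#' EUR, computes the value-based price at the primary and secondary
#' thresholds, compares the primary price with the real market price and
#' classifies concordance. Failures on one device are captured in its
#' `warnings` field without aborting the batch; the run is deterministic
#' and preserves input order.
#'
#' @inheritParams screen_portfolio
#' @param rates an [exchange_rate_table()].
#' @param wtp_primary,wtp_secondary thresholds in EUR/QALY (defaults
#'   60,000 and 30,000); secondary must not exceed primary.
#' @param band_fraction concordance band half-width (default 0.2).
#' @return a list of class `vbp_run`: `results`, a `data.frame` with one
#'   row per eligible device (unrounded EUR prices, ratio, concordance,
#'   semicolon-joined warning flags), and `summary`, the screening summary.
#' @export
run_pipeline <- function(records, rates, wtp_primary = 60000,
                         wtp_secondary = 30000, band_fraction = 0.2) {
  wp <- as_wtp(wtp_primary); ws <- as_wtp(wtp_secondary)
  if (ws > wp)
    stop_domain("the secondary threshold must not exceed the primary threshold")
  scr <- screen_portfolio(records)
  elig <- scr$eligible
  rows <- vector("list", nrow(elig))
  for (i in seq_len(nrow(elig))) {
    rec <- elig[i, ]
    flags <- character(0)
    res <- tryCatch(
      withCallingHandlers({
        inp <- cea_inputs_to_eur(record_to_cea_inputs(rec), rates)
        real <- to_eur(money(rec$real_price, rec$real_price_currency), rates)$amount
        band <- price_band(inp, wp, ws)
        conc <- if (band[["high"]] > 0 && real > 0)
          classify_concordance(band[["high"]], real, band_fraction)
        else NA_character_
        list(vbp_secondary = band[["low"]], vbp_primary = band[["high"]],
             real = real,
             ratio = if (band[["high"]] > 0) real / band[["high"]] else NA_real_,
             concordance = conc)
      }, vbp_warning = function(w) {
        flags <<- union(flags, w$flag)
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        flags <<- union(flags, paste0("error: ", conditionMessage(e)))
        list(vbp_secondary = NA_real_, vbp_primary = NA_real_,
             real = NA_real_, ratio = NA_real_, concordance = NA_character_)
      })
    rows[[i]] <- data.frame(
      device_id = rec$device_id, name = rec$name,
      vbp_secondary_eur = res$vbp_secondary, vbp_primary_eur = res$vbp_primary,
      real_price_eur = res$real, ratio_real_to_vbp_primary = res$ratio,
      concordance = res$concordance,
      warnings = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(device_id = character(0), name = character(0),
               vbp_secondary_eur = numeric(0), vbp_primary_eur = numeric(0),
               real_price_eur = numeric(0), ratio_real_to_vbp_primary = numeric(0),
               concordance = character(0), warnings = character(0),
               stringsAsFactors = FALSE)
  rownames(results) <- NULL
  structure(list(results = results, summary = scr$summary,
                 wtp_primary = wp, wtp_secondary = ws,
                 band_fraction = band_fraction),
            class = "vbp_run")
}

#' @export
print.vbp_run <- function(x, ...) {
  print(x$summary)
  if (nrow(x$results)) {
    shown <- x$results
    for (col in c("vbp_secondary_eur", "vbp_primary_eur", "real_price_eur"))
      shown[[col]] <- round_half_up(shown[[col]])
    shown$ratio_real_to_vbp_primary <- round(shown$ratio_real_to_vbp_primary, 2)
    print(shown, row.names = FALSE)
    tally <- table(factor(x$results$concordance,
                          levels = c("concordant", "real_above_vbp", "vbp_above_real")))
    cat(sprintf("Concordance (+/-%d%% band): %d concordant, %d real above VBP, %d VBP above real\n",
                round(100 * x$band_fraction), tally[["concordant"]],
                tally[["real_above_vbp"]], tally[["vbp_above_real"]]))
  }
  invisible(x)
}

#' Long-format price table for plotting
#'
#' Reshapes a pipeline run into one row per device and price series (real
#' price, value-based price at each threshold) — the numeric table behind
#' a grouped bar chart of value-based versus real prices.
#'
#' @param run a `vbp_run` from [run_pipeline()].
#' @return a `data.frame` with columns `device_id`, `series`, `price_eur`
#'   (whole euros).
#' @export
results_long <- function(run) {
  if (!inherits(run, "vbp_run")) stop_domain("run must be a vbp_run")
  r <- run$results
  out <- data.frame(
    device_id = rep(r$device_id, 3L),
    series = rep(c(sprintf("vbp_wtp_%d", round(run$wtp_secondary)),
                   sprintf("vbp_wtp_%d", round(run$wtp_primary)),
                   "real_price"), each = nrow(r)),
    price_eur = round_half_up(c(r$vbp_secondary_eur, r$vbp_primary_eur,
                                r$real_price_eur)),
    stringsAsFactors = FALSE)
  out[order(match(out$device_id, r$device_id)), , drop = FALSE]
}

#' Write pipeline results to CSV
#'
#' Writes the per-device results (prices rounded to whole euros, ratio to
#' 4 decimals, warning flags semicolon-joined) and, optionally, the
#' long-format price table from [results_long()]. Output is UTF-8 with "."
#' decimals and is byte-identical across runs on identical inputs.
#'
#' @param run a `vbp_run` from [run_pipeline()].
#' @param path output CSV path for the per-device table.
#' @param figure_path optional path for the long-format price table.
#' @return `path`, invisibly.
#' @export
write_results <- function(run, path, figure_path = NULL) {
  if (!inherits(run, "vbp_run")) stop_domain("run must be a vbp_run")
  out <- run$results
  for (col in c("vbp_secondary_eur", "vbp_primary_eur", "real_price_eur"))
    out[[col]] <- round_half_up(out[[col]])
  out$ratio_real_to_vbp_primary <- round_half_up(out$ratio_real_to_vbp_primary, 4)
  tryCatch({
    write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  }, error = function(e) {
    stop_vbp(sprintf("cannot write results to %s: %s", path, conditionMessage(e)),
             "vbp_io_error")
  })
  if (!is.null(figure_path)) {
    lng <- results_long(run)
    write.csv(lng, figure_path, row.names = FALSE, quote = TRUE,
              fileEncoding = "UTF-8")
  }
  invisible(path)
}
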