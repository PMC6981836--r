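#' Daily exposure-response series
#'
#' The core container used throughout the package: aligned daily vectors of
#' calendar date, health outcome (a count for the Poisson family, a real
#' response for the Gaussian family), exposure concentration and, optionally,
#' ambient temperature.
#'
#' Dates must be strictly increasing. Calendar gaps are allowed but flagged
#' with a warning, because strata built from day-of-year blocks then contain
#' fewer records than their nominal window. Missing outcome or exposure
#' values are retained here and excluded later, at stratification time.
#'
#' @param dates `Date` vector, strictly increasing.
#' @param outcome numeric vector of per-day responses. May contain `NA`.
#' @param exposure numeric vector of per-day concentrations. May contain `NA`.
#' @param temperature optional numeric vector of per-day temperatures
#'   (degrees Celsius).
#' @param meta named list of free-form labels (series id, source, ...).
#' @param family `"gaussian"` or `"poisson"`; under `"poisson"` the non-`NA`
#'   outcomes must be non-negative integers.
#' @return An object of class `daily_series`: a data frame with columns
#'   `date`, `outcome`, `exposure` and (if supplied) `temperature`, plus a
#'   `meta` attribute. The internal day index is 0-based from the first date.
#' @examples
#' d <- daily_series(as.Date("2019-01-01") + 0:3,
#'                   outcome = c(3, 1, 2, 5),
#'                   exposure = c(10, 12, 9, 11))
#' d
#' @export
daily_series <- function(dates, outcome, exposure, temperature = NULL,
                         meta = list(), family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  dates <- as.Date(dates)
  n <- length(dates)
  if (n < 1L) stop("a daily series needs at least one day", call. = FALSE)
  if (length(outcome) != n || length(exposure) != n)
    stop("dates, outcome and exposure must have identical length", call. = FALSE)
  if (!is.null(temperature) && length(temperature) != n)
    stop("temperature must have the same length as dates", call. = FALSE)
  if (anyNA(dates)) stop("dates must not contain NA", call. = FALSE)
  if (n > 1L && any(diff(as.integer(dates)) <= 0)) {
    if (anyDuplicated(dates)) stop("duplicate dates in series", call. = FALSE)
    stop("dates must be strictly increasing", call. = FALSE)
  }
  outcome <- as.numeric(outcome)
  exposure <- as.numeric(exposure)
  if (family == "poisson") {
    ok <- is.na(outcome) | (outcome >= 0 & outcome == round(outcome))
    if (!all(ok))
      stop("poisson family requires non-negative integer outcomes; offending rows: ",
           paste(utils::head(which(!ok), 5L), collapse = ", "), call. = FALSE)
  }
  gaps <- if (n > 1L) sum(diff(as.integer(dates)) - 1L) else 0L
  if (gaps > 0L)
    warning(sprintf("series has %d missing calendar day(s) between %s and %s",
                    gaps, format(dates[1L]), format(dates[n])), call. = FALSE)
  out <- data.frame(date = dates, outcome = outcome, exposure = exposure)
  if (!is.null(temperature)) out$temperature <- as.numeric(temperature)
  attr(out, "meta") <- meta
  attr(out, "family") <- family
  class(out) <- c("daily_series", "data.frame")
  out
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("daily_series: %d days, %s .. %s%s\n",
              nrow(x), format(x$date[1L]), format(x$date[nrow(x)]),
              if ("temperature" %in% names(x)) ", with temperature" else ""))
  nm <- attr(x, "meta")
  if (length(nm)) cat("meta:", paste(names(nm), unlist(nm), sep = "=", collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Series reading configuration
#'
#' Maps CSV columns onto the fields of a [daily_series] and records the model
#' family and exposure lag. The loader is configuration-driven because
#' published daily-series files do not share a fixed column layout.
#'
#' @param date_col,outcome_col,exposure_col,temperature_col column names in
#'   the CSV; `temperature_col = NULL` means no temperature column.
#' @param date_format parse pattern for [base::as.Date()].
#' @param family `"gaussian"` or `"poisson"`.
#' @param lag non-negative integer number of days the exposure is lagged.
#' @return A list of class `series_config`.
#' @export
series_config <- function(date_col = "date", outcome_col = "outcome",
                          exposure_col = "exposure", temperature_col = NULL,
                          date_format = "%Y-%m-%d",
                          family = c("gaussian", "poisson"), lag = 0L) {
  family <- match.arg(family)
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 0L) stop("lag must be a non-negative integer", call. = FALSE)
  structure(list(date_col = date_col, outcome_col = outcome_col,
                 exposure_col = exposure_col, temperature_col = temperature_col,
                 date_format = date_format, family = family, lag = lag),
            class = "series_config")
}

#' Read a series configuration from a JSON or YAML file
#'
#' The file holds any subset of the [series_config()] arguments.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return A `series_config`.
#' @export
read_series_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(series_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(series_config, raw)
}

#' Read a daily series from CSV
#'
#' Reads a comma-separated file with a header row and builds a validated
#' [daily_series]. Rows whose date does not parse under the configured format
#' are rejected, with the count reported to stderr; a duplicate date is an
#' error; missing calendar days are allowed but flagged. The configured
#' exposure lag is *not* applied here -- use [apply_lag()] explicitly.
#'
#' @param path CSV file path.
#' @param config a [series_config()].
#' @param verbose emit a note about rejected rows (default `TRUE`).
#' @return A [daily_series].
#' @export
read_daily_csv <- function(path, config = series_config(), verbose = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(config, "series_config"))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  need <- c(config$date_col, config$outcome_col, config$exposure_col,
            config$temperature_col)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("configured column(s) not in file: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dates <- as.Date(as.character(tab[[config$date_col]]), format = config$date_format)
  bad <- is.na(dates)
  if (any(bad)) {
    if (verbose)
      message(sprintf("read_daily_csv: rejected %d row(s) with unparseable dates", sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
    dates <- dates[!bad]
  }
  if (!length(dates)) stop("no parseable rows in ", path, call. = FALSE)
  if (anyDuplicated(dates)) stop("duplicate date(s) in ", path, call. = FALSE)
  o <- order(dates)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]][o]))
    conv_bad <- !is.na(tab[[col]][o]) & tab[[col]][o] != "" & is.na(v)
    if (any(conv_bad))
      stop(sprintf("non-numeric value(s) in column '%s' of %s", col, path), call. = FALSE)
    v
  }
  daily_series(dates[o], num(config$outcome_col), num(config$exposure_col),
               temperature = if (!is.null(config$temperature_col)) num(config$temperature_col),
               meta = list(source = path), family = config$family)
}

#' Write a daily series to CSV
#'
#' The inverse of [read_daily_csv()] under the same column mapping: numbers
#' are written with 17 significant digits so a read/write cycle round-trips
#' every value exactly.
#'
#' @param series a [daily_series].
#' @param path output path.
#' @param config a [series_config()] naming the output columns.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(series, path, config = series_config()) {
  stopifnot(inherits(series, "daily_series"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- data.frame(format(series$date, config$date_format),
                    fmt(series$outcome), fmt(series$exposure),
                    stringsAsFactors = FALSE, check.names = FALSE)
  nms <- c(config$date_col, config$outcome_col, config$exposure_col)
  if ("temperature" %in% names(series) && !is.null(config$temperature_col)) {
    out[[4L]] <- fmt(series$temperature)
    nms <- c(nms, config$temperature_col)
  }
  names(out) <- nms
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Lag the exposure series
#'
#' Replaces the exposure on day t by the exposure on day t - lag and drops
#' the first `lag` days from every vector, so outcome on day t is paired with
#' exposure `lag` days earlier. `lag = 0` is the identity.
#'
#' @param series a [daily_series].
#' @param lag non-negative integer, strictly smaller than the series length.
#' @return A [daily_series] of length `nrow(series) - lag`.
#' @export
apply_lag <- function(series, lag) {
  stopifnot(inherits(series, "daily_series"))
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 0L) stop("lag must be a non-negative integer", call. = FALSE)
  if (lag == 0L) return(series)
  n <- nrow(series)
  if (lag >= n) stop("lag (", lag, ") must be smaller than the series length (", n, ")",
                     call. = FALSE)
  keep <- (lag + 1L):n
  out <- as.data.frame(series)[keep, , drop = FALSE]
  out$exposure <- series$exposure[keep - lag]
  rownames(out) <- NULL
  attr(out, "meta") <- c(attr(series, "meta"), list(lag = lag))
  attr(out, "family") <- attr(series, "family")
  class(out) <- c("daily_series", "data.frame")
  out
}
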