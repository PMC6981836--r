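#' Calendar stratification schemes
#'
#' A stratum scheme names the calendar rule that groups days into
#' exchangeable sets for the case-crossover comparison:
#'
#' * `CC2D` -- pairs of consecutive days within a year: (1,2), (3,4), ...;
#'   the shortest possible time-window. A 365-day year gives 183 strata
#'   (182 pairs plus a trailing singleton).
#' * `CC3D` -- triples of consecutive days within a year.
#' * `CC2W` -- `<year : two-week block : day of week>`; each stratum holds at
#'   most two days, one week apart.
#' * `CC2CW` -- chained two-week blocks (1,2), (2,3), (3,4), ... crossed with
#'   day of week; every interior week's days appear in two strata.
#' * `CCM` -- the classical time-stratified window
#'   `<calendar year : month : day of week>`.
#'
#' `year_rule` chooses how a "year" is delimited: `"calendar"` uses calendar
#' years (day-of-year 1..366, suitable for real data); `"fixed365"` cuts the
#' series into consecutive 365-day blocks from its first day (suitable for
#' simulated series of exact 365-day years). `CCM` always uses the calendar
#' year and month of the actual dates, since a month is a calendar notion.
#'
#' @param name one of `"CC2D"`, `"CC3D"`, `"CC2W"`, `"CC2CW"`, `"CCM"`.
#' @param year_rule `"calendar"` or `"fixed365"`.
#' @param allow_partial_year under `"fixed365"`, permit a trailing block
#'   shorter than 365 days (default `FALSE`).
#' @return A list of class `stratum_scheme` with elements `name`,
#'   `block_days` (2 for CC2D, 3 for CC3D, `NA` otherwise), `year_rule`,
#'   `allow_partial_year`.
#' @export
stratum_scheme <- function(name = c("CC2D", "CC3D", "CC2W", "CC2CW", "CCM"),
                           year_rule = c("calendar", "fixed365"),
                           allow_partial_year = FALSE) {
  name <- match.arg(toupper(name), c("CC2D", "CC3D", "CC2W", "CC2CW", "CCM"))
  year_rule <- match.arg(year_rule)
  structure(list(name = name,
                 block_days = switch(name, CC2D = 2L, CC3D = 3L, NA_integer_),
                 year_rule = year_rule,
                 allow_partial_year = isTRUE(allow_partial_year)),
            class = "stratum_scheme")
}

#' @export
print.stratum_scheme <- function(x, ...) {
  cat(sprintf("stratum_scheme %s (year_rule=%s%s)\n", x$name, x$year_rule,
              if (!is.na(x$block_days)) paste0(", block_days=", x$block_days) else ""))
  invisible(x)
}

# Day-of-week as integer 1..7, Monday = 1, locale-independent.
day_of_week <- function(dates) {
  (as.POSIXlt(dates)$wday + 6L) %% 7L + 1L
}

dow_labels <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

# Year label and day-of-year under the scheme's year rule.
year_and_doy <- function(dates, scheme) {
  if (scheme$year_rule == "calendar") {
    lt <- as.POSIXlt(dates)
    list(year = sprintf("%04d", lt$year + 1900L), doy = lt$yday + 1L)
  } else {
    idx <- as.integer(dates - dates[1L])
    n <- length(dates)
    span <- as.integer(dates[n] - dates[1L]) + 1L
    if (span %% 365L != 0L && !scheme$allow_partial_year)
      stop("year_rule = 'fixed365' needs a series span divisible by 365 days ",
           "(span is ", span, "); set allow_partial_year = TRUE to permit a ",
           "short trailing block", call. = FALSE)
    list(year = sprintf("Y%02d", idx %/% 365L + 1L), doy = idx %% 365L + 1L)
  }
}

#' Assign days to case-crossover strata
#'
#' Builds the stratified dataset a conditional fit consumes: one record per
#' (day, stratum) membership, labelled with a deterministic stratum id of the
#' form `"<year>:<block>"` or `"<year>:<block>:<dow>"`. Records with missing
#' outcome or exposure are excluded before grouping. For the chained scheme
#' `CC2CW` interior weeks are duplicated into their two neighbouring strata,
#' so a day can yield two records; all other schemes partition the retained
#' days.
#'
#' @param series a [daily_series].
#' @param scheme a [stratum_scheme()].
#' @return An object of class `stratified_data`: a data frame with columns
#'   `day` (0-based index in the source series), `date`, `outcome`,
#'   `exposure`, `temperature` (if present), `dow` (factor, Mon..Sun) and
#'   `stratum` (factor), with attributes `scheme`, `n_strata` and
#'   `duplication` (per-day membership counts).
#' @examples
#' s <- daily_series(as.Date("2019-01-01") + 0:9, rnorm(10), rnorm(10))
#' assign_strata(s, stratum_scheme("CC2D"))
#' @export
assign_strata <- function(series, scheme) {
  stopifnot(inherits(series, "daily_series"), inherits(scheme, "stratum_scheme"))
  keep <- !is.na(series$outcome) & !is.na(series$exposure)
  if (!any(keep)) stop("no record has both outcome and exposure observed", call. = FALSE)
  dat <- as.data.frame(series)  # keep full series for the year rule, subset after
  yd <- year_and_doy(dat$date, scheme)
  dat$day <- seq_len(nrow(dat)) - 1L
  dat$dow <- factor(dow_labels[day_of_week(dat$date)], levels = dow_labels)
  dat$year <- yd$year
  dat$doy <- yd$doy
  dat <- dat[keep, , drop = FALSE]

  dowtag <- as.character(dat$dow)
  recs <- switch(scheme$name,
    CC2D = ,
    CC3D = {
      block <- (dat$doy - 1L) %/% scheme$block_days + 1L
      dat$stratum <- sprintf("%s:%03d", dat$year, block)
      dat
    },
    CC2W = {
      week <- (dat$doy - 1L) %/% 7L + 1L
      block <- (week - 1L) %/% 2L + 1L
      dat$stratum <- sprintf("%s:%02d:%s", dat$year, block, dowtag)
      dat
    },
    CC2CW = {
      week <- (dat$doy - 1L) %/% 7L + 1L
      last_week <- stats::ave(week, dat$year, FUN = max)
      # chained pairs (w-1, w) and (w, w+1): week w joins chain w-1 and chain w
      lhs <- dat[week > 1L, , drop = FALSE]
      lhs$stratum <- sprintf("%s:%02d:%s", lhs$year, week[week > 1L] - 1L,
                             dowtag[week > 1L])
      rhs <- dat[week < last_week, , drop = FALSE]
      rhs$stratum <- sprintf("%s:%02d:%s", rhs$year, week[week < last_week],
                             dowtag[week < last_week])
      rbind(lhs, rhs)
    },
    CCM = {
      lt <- as.POSIXlt(dat$date)
      dat$stratum <- sprintf("%04d:%02d:%s", lt$year + 1900L, lt$mon + 1L, dowtag)
      dat
    })

  recs <- recs[order(recs$stratum, recs$day), , drop = FALSE]
  rownames(recs) <- NULL
  cols <- c("day", "date", "outcome", "exposure",
            if ("temperature" %in% names(recs)) "temperature", "dow", "stratum")
  recs <- recs[, cols]
  recs$stratum <- factor(recs$stratum)
  attr(recs, "scheme") <- scheme
  attr(recs, "n_strata") <- nlevels(recs$stratum)
  attr(recs, "duplication") <- table(recs$day)
  attr(recs, "family") <- attr(series, "family")
  class(recs) <- c("stratified_data", "data.frame")
  recs
}

#' @export
print.stratified_data <- function(x, ...) {
  sch <- attr(x, "scheme")
  cat(sprintf("stratified_data: %d records in %d strata (scheme %s)\n",
              nrow(x), attr(x, "n_strata"), sch$name))
  rem <- attr(x, "removed")
  if (!is.null(rem))
    cat("uninformative strata removed:",
        paste(names(rem), unlist(rem), sep = "=", collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Drop strata that cannot inform the slope
#'
#' A stratum contributes to the conditional likelihood only if it has at
#' least two records and its exposure varies across them; under the Poisson
#' family a stratum whose outcomes sum to zero also drops out (its
#' multinomial term is empty). Removal counts are recorded by reason in the
#' `removed` attribute; a stratum failing several tests is counted under the
#' first (size, then constant exposure, then zero outcome).
#'
#' @param ds a `stratified_data` from [assign_strata()].
#' @param family `"gaussian"` or `"poisson"`.
#' @return The filtered `stratified_data` (possibly with zero rows).
#' @export
informative_strata <- function(ds, family = c("gaussian", "poisson")) {
  stopifnot(inherits(ds, "stratified_data"))
  family <- match.arg(family)
  if (!is.null(attr(ds, "removed"))) return(ds)  # already filtered
  s <- ds$stratum
  size <- tapply(ds$exposure, s, length)
  xspan <- tapply(ds$exposure, s, function(v) max(v) - min(v))
  ytot <- tapply(ds$outcome, s, sum)
  too_small <- size < 2L
  const_x <- !too_small & xspan == 0
  zero_y <- family == "poisson" & !too_small & !const_x & ytot == 0
  drop <- too_small | const_x | zero_y
  keep_levels <- names(size)[!drop]
  out <- ds[as.character(s) %in% keep_levels, , drop = FALSE]
  rownames(out) <- NULL
  out$stratum <- factor(as.character(out$stratum), levels = keep_levels)
  attr(out, "scheme") <- attr(ds, "scheme")
  attr(out, "n_strata") <- nlevels(out$stratum)
  attr(out, "duplication") <- table(out$day)
  attr(out, "family") <- attr(ds, "family")
  attr(out, "removed") <- list(too_small = sum(too_small),
                               constant_exposure = sum(const_x),
                               zero_outcome = sum(zero_y))
  class(out) <- c("stratified_data", "data.frame")
  out
}

#' Export a stratified dataset for audit
#'
#' One CSV row per record with its stratum id, so the exact grouping a fit
#' used can be inspected outside R.
#'
#' @param ds a `stratified_data`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_strata_csv <- function(ds, path) {
  stopifnot(inherits(ds, "stratified_data"))
  out <- as.data.frame(ds)
  out$date <- format(out$date, "%Y-%m-%d")
  out$dow <- as.character(out$dow)
  out$stratum <- as.character(out$stratum)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
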