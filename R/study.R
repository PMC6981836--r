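#' Fit one method to one daily series
#'
#' Dispatch helper used by the study harness: conditional fits for the
#' case-crossover schemes (`"CC2D"`, `"CC3D"`, `"CC2W"`, `"CC2CW"`,
#' `"CCM"`), spline-adjusted time-series GLM for `"GLM6"` / `"GLM12"` (or
#' any `"GLM<df>"`).
#'
#' @param series a [daily_series].
#' @param method a method name as above (case-insensitive).
#' @param spec a [model_spec()].
#' @param year_rule passed to [stratum_scheme()] for the CC schemes.
#' @return A `cc_fit`.
#' @export
fit_method <- function(series, method, spec = model_spec("gaussian"),
                       year_rule = "fixed365") {
  method <- toupper(method)
  if (grepl("^GLM[0-9]+$", method)) {
    df <- as.numeric(sub("GLM", "", method))
    return(fit_time_series_glm(series, spec, df_per_year = df))
  }
  scheme <- stratum_scheme(method, year_rule = year_rule)
  ds <- assign_strata(series, scheme)
  if (spec$family == "poisson") fit_conditional_poisson(ds, spec)
  else fit_conditional_gaussian(ds, spec)
}

#' Run a simulation study over one scenario
#'
#' Applies each method to every sample, collects the per-sample slope
#' estimates and standard errors, and summarises them with the six order
#' statistics (minimum, first quartile, median, mean, third quartile,
#' maximum; quartiles by linear interpolation between order statistics)
#' plus the across-sample standard deviation of the slopes. Non-converged
#' fits are excluded from the summaries and counted, never imputed.
#'
#' @param samples list of `sim_sample` objects (from [generate_study_set()]
#'   or [load_published_samples()]).
#' @param methods character vector of method names for [fit_method()].
#' @param spec a [model_spec()] (Gaussian for the simulated series).
#' @param year_rule year delimitation for the CC schemes; the default
#'   `"fixed365"` matches simulated series of exact 365-day years.
#' @return A list of `study_summary` objects, one per method, each with
#'   elements `method`, `sim_id`, `stats_beta`, `stats_se`, `sd_beta`,
#'   `n_samples`, `n_failed`, `valid`, and the raw per-sample vectors
#'   `betas`, `ses`.
#' @export
run_simulation_study <- function(samples, methods, spec = model_spec("gaussian"),
                                 year_rule = "fixed365") {
  stopifnot(length(samples) >= 1L, length(methods) >= 1L)
  sim_id <- attr(samples[[1L]]$series, "meta")$sim_id %||% "data"
  lapply(methods, function(m) {
    betas <- rep(NA_real_, length(samples))
    ses <- rep(NA_real_, length(samples))
    for (i in seq_along(samples)) {
      fit <- suppressMessages(fit_method(samples[[i]]$series, m, spec, year_rule))
      if (isTRUE(fit$converged)) {
        betas[i] <- fit$beta
        ses[i] <- fit$se
      }
    }
    ok <- !is.na(betas)
    six <- function(v) {
      if (!any(ok)) return(stats::setNames(rep(NA_real_, 6L), summary_stat_names))
      q <- stats::quantile(v[ok], c(0, .25, .5, .75, 1), type = 7, names = FALSE)
      stats::setNames(c(q[1L], q[2L], q[3L], mean(v[ok]), q[4L], q[5L]),
                      summary_stat_names)
    }
    structure(list(method = toupper(m), sim_id = sim_id,
                   stats_beta = six(betas), stats_se = six(ses),
                   sd_beta = if (any(ok)) stats::sd(betas[ok]) else NA_real_,
                   n_samples = length(samples), n_failed = sum(!ok),
                   valid = any(ok), betas = betas, ses = ses),
              class = "study_summary")
  })
}

summary_stat_names <- c("Minimum", "1stQuartile", "Median", "Mean",
                        "3rdQuartile", "Maximum")

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("study_summary: %s on sim %s (%d samples, %d failed)%s\n",
              x$method, x$sim_id, x$n_samples, x$n_failed,
              if (!x$valid) " [INVALID: all fits failed]" else ""))
  print(round(rbind(beta = x$stats_beta, se = x$stats_se), 4))
  invisible(x)
}

#' Tabulate study summaries in the stacked beta/SE layout
#'
#' One 12-row block per method: six order-statistic rows for the slope
#' (columns `Beta<sim>`) stacked over six rows for the standard errors
#' (columns `SE<sim>`), with values rounded to `digits` decimals. Scenarios
#' absent for a method render as `NA`.
#'
#' @param summaries a flat list of `study_summary` objects (possibly several
#'   scenarios per method).
#' @param digits decimals to round to (default 4, the conventional
#'   presentation); `NA` keeps full precision.
#' @return A data frame with columns `method`, `block` (`"Beta"`/`"SE"`),
#'   `parameter` (the six statistic names) and one value column per
#'   scenario.
#' @export
summarize_to_table <- function(summaries, digits = 4) {
  stopifnot(length(summaries) >= 1L)
  methods <- unique(vapply(summaries, function(s) s$method, ""))
  sims <- unique(vapply(summaries, function(s) as.character(s$sim_id), ""))
  rnd <- function(v) if (is.na(digits)) v else round(v, digits)
  blocks <- lapply(methods, function(m) {
    vals_b <- matrix(NA_real_, 6L, length(sims),
                     dimnames = list(summary_stat_names, sims))
    vals_s <- vals_b
    for (s in summaries) {
      if (s$method != m) next
      sid <- as.character(s$sim_id)
      if (s$valid) {
        vals_b[, sid] <- rnd(s$stats_beta)
        vals_s[, sid] <- rnd(s$stats_se)
      }
    }
    rbind(data.frame(method = m, block = "Beta", parameter = summary_stat_names,
                     vals_b, check.names = FALSE, row.names = NULL),
          data.frame(method = m, block = "SE", parameter = summary_stat_names,
                     vals_s, check.names = FALSE, row.names = NULL))
  })
  out <- do.call(rbind, blocks)
  names(out)[-(1:3)] <- paste0("Sim", sims)
  out
}

#' Write / render a summary table
#'
#' `write_summary_csv()` writes the table from [summarize_to_table()] so
#' that reading it back recovers the numbers exactly;
#' `format_summary_markdown()` renders it as a GitHub-style markdown table.
#'
#' @param table a data frame from [summarize_to_table()].
#' @param path output path.
#' @return `path` invisibly, or a character vector of markdown lines.
#' @export
write_summary_csv <- function(table, path) {
  num <- vapply(table, is.numeric, TRUE)
  out <- table
  out[num] <- lapply(out[num], function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
format_summary_markdown <- function(table) {
  num <- vapply(table, is.numeric, TRUE)
  tab <- table
  tab[num] <- lapply(tab[num], function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v)))
  tab[] <- lapply(tab, as.character)
  header <- paste0("| ", paste(names(tab), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  rows <- apply(tab, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, rows)
}

#' Epidemiological count-series analysis
#'
#' The real-data pipeline: optionally lag the exposure, stratify the daily
#' counts under the chosen calendar scheme, filter uninformative strata and
#' fit the conditional Poisson model. Day-of-week is adjusted by a factor
#' covariate where it varies within strata (CC2D, CC3D) and is absorbed by
#' the design -- hence automatically dropped with a notice -- where it is a
#' stratum level (CC2W, CC2CW, CCM). Ambient temperature, when present and
#' requested, enters through a natural cubic spline (3 df is conventional).
#'
#' @param series a [daily_series] of daily counts.
#' @param scheme a [stratum_scheme()].
#' @param spec a [model_spec()] with `family = "poisson"`.
#' @param lag non-negative exposure lag in days.
#' @return A `cc_fit`.
#' @export
run_epi_analysis <- function(series, scheme, spec = model_spec("poisson"),
                             lag = 0L) {
  stopifnot(inherits(series, "daily_series"), inherits(scheme, "stratum_scheme"))
  if (spec$family != "poisson")
    stop("run_epi_analysis fits daily counts; spec$family must be 'poisson'",
         call. = FALSE)
  if (lag > 0L) series <- apply_lag(series, lag)
  ds <- assign_strata(series, scheme)
  fit_conditional_poisson(ds, spec)
}
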