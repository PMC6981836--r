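#' Configuration of the seasonal-confounding simulator
#'
#' The simulator generates exposure-response series with a known slope and a
#' periodic confounder that shares the exposure's mid-range frequencies, the
#' structure under which spline-adjusted time-series regression is known to
#' fail while short-window conditional designs are not. Four scenarios are
#' predefined:
#'
#' * `sim_id = 1`: exposure and confounder share periodicities at 183 and
#'   75 days, white background noise;
#' * `sim_id = 2`: scenario 1 plus additional shared signals at periods 105
#'   and 68 days;
#' * `sim_id = 3`: scenario 2 with autocorrelated (AR(1)) background noise
#'   in place of white noise;
#' * `sim_id = 4`: scenario 3 with both background noises scaled up by a
#'   factor of 2.
#'
#' Every generative constant is an explicit, documented argument -- none is
#' a published value; the defaults are chosen once to reproduce the
#' qualitative structure (see the package vignette for the reasoning).
#' Exposure on day t is
#' `x_t = sum_k a_k sin(2 pi t / P_k + phi_k) + e_t` and the outcome is
#' `y_t = beta_true x_t + sum_k b_k sin(2 pi t / P_k + psi_k) + eps_t`, with
#' `psi_k = phi_k + phase_offset` so the shared periodicities confound.
#'
#' @param sim_id scenario 1..4; presets `periods`, `noise_model` and
#'   `noise_scale` unless those are supplied explicitly.
#' @param n_years,days_per_year series dimensions (defaults 10 x 365, i.e.
#'   3650 days).
#' @param beta_true the true slope (default 1).
#' @param periods confounder/exposure shared periods in days (all >= 2).
#' @param exposure_amplitudes,confounder_amplitudes per-period sinusoid
#'   amplitudes `a_k`, `b_k` (recycled; all >= 0).
#' @param phases exposure phases `phi_k` in radians (recycled), or
#'   `"random"` to draw them uniformly per sample.
#' @param phase_offset `psi_k - phi_k`, the confounder's phase shift
#'   (default 2*pi/3, so the confounder partially opposes the exposure).
#' @param noise_model `"white"`, `"ar1"` or `"mixture"` (a 10 percent
#'   3-sigma contaminated normal); applies to both noise streams.
#' @param noise_sd_exposure,noise_sd_outcome marginal noise standard
#'   deviations before scaling.
#' @param noise_scale common multiplier on both noise sds (scenario 4 uses 2).
#' @param ar1_coef lag-1 autocorrelation under `noise_model = "ar1"`.
#' @param start_date first calendar day of each series.
#' @param seed master seed; per-sample streams are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sim_id = 1L, n_years = 10L, days_per_year = 365L,
                       beta_true = 1.0, periods = NULL,
                       exposure_amplitudes = 1.0, confounder_amplitudes = 1.5,
                       phases = 0, phase_offset = 2 * pi / 3,
                       noise_model = NULL, noise_sd_exposure = 0.5,
                       noise_sd_outcome = 0.1, noise_scale = NULL,
                       ar1_coef = 0.7, start_date = as.Date("2001-01-01"),
                       seed = 1L) {
  sim_id <- as.integer(sim_id)
  if (is.na(sim_id) || !sim_id %in% 1:4) stop("sim_id must be 1, 2, 3 or 4", call. = FALSE)
  if (is.null(periods))
    periods <- if (sim_id == 1L) c(183, 75) else c(183, 75, 105, 68)
  if (any(periods < 2)) stop("all periods must be at least 2 days", call. = FALSE)
  if (is.null(noise_model)) noise_model <- if (sim_id >= 3L) "ar1" else "white"
  noise_model <- match.arg(noise_model, c("white", "ar1", "mixture"))
  if (is.null(noise_scale)) noise_scale <- if (sim_id == 4L) 2 else 1
  k <- length(periods)
  rec <- function(v) rep_len(v, k)
  if (any(exposure_amplitudes < 0) || any(confounder_amplitudes < 0))
    stop("amplitudes must be non-negative", call. = FALSE)
  structure(list(sim_id = sim_id, n_years = as.integer(n_years),
                 days_per_year = as.integer(days_per_year),
                 n_days = as.integer(n_years) * as.integer(days_per_year),
                 beta_true = beta_true, periods = periods,
                 exposure_amplitudes = rec(exposure_amplitudes),
                 confounder_amplitudes = rec(confounder_amplitudes),
                 phases = phases, phase_offset = phase_offset,
                 noise_model = noise_model,
                 noise_sd_exposure = noise_sd_exposure,
                 noise_sd_outcome = noise_sd_outcome,
                 noise_scale = noise_scale, ar1_coef = ar1_coef,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic per-sample seed below 2^31, derived from (master seed, index).
derive_seed <- function(seed, sample_index) {
  as.integer(((abs(as.numeric(seed)) %% 2147483647) * 48271 +
                as.numeric(sample_index) * 1299709) %% 2147483647) + 1L
}

sim_noise <- function(n, sd, model, ar1_coef) {
  if (sd == 0) return(numeric(n))
  switch(model,
    white = stats::rnorm(n, 0, sd),
    ar1 = {
      # innovations scaled so the marginal sd stays `sd`
      z <- stats::rnorm(n, 0, sd * sqrt(1 - ar1_coef^2))
      as.numeric(stats::filter(z, ar1_coef, method = "recursive",
                               init = stats::rnorm(1, 0, sd)))
    },
    mixture = {
      wide <- stats::runif(n) < 0.1
      s <- sd / sqrt(0.9 + 0.1 * 9)   # keep the marginal sd at `sd`
      stats::rnorm(n, 0, ifelse(wide, 3 * s, s))
    })
}

#' Generate one simulated exposure-response sample
#'
#' Draws one series under a [sim_config()]. The latent decomposition
#' (periodic exposure signal, exposure noise, confounder, outcome noise) is
#' retained in `$truth`, and the outcome is constructed exactly as
#' `beta_true * exposure + confounder + noise`, so it is reconstructible
#' from the stored components to the last bit.
#'
#' @param config a [sim_config()].
#' @param sample_index non-negative integer; combined with the master seed
#'   it selects a reproducible per-sample random stream.
#' @return A list of class `sim_sample` with elements `series` (a
#'   [daily_series], Gaussian family) and `truth` (list: `beta_true`,
#'   `signal`, `exposure_noise`, `confounder`, `outcome_noise`).
#' @export
generate_sample <- function(config, sample_index = 0L) {
  stopifnot(inherits(config, "sim_config"))
  sample_index <- as.integer(sample_index)
  if (is.na(sample_index) || sample_index < 0L)
    stop("sample_index must be a non-negative integer", call. = FALSE)
  n <- config$n_days
  t <- seq_len(n)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(derive_seed(config$seed, sample_index))
  phi <- if (identical(config$phases, "random"))
    stats::runif(length(config$periods), 0, 2 * pi)
  else rep_len(config$phases, length(config$periods))
  psi <- phi + config$phase_offset
  signal <- numeric(n)
  confounder <- numeric(n)
  for (k in seq_along(config$periods)) {
    w <- 2 * pi * t / config$periods[k]
    signal <- signal + config$exposure_amplitudes[k] * sin(w + phi[k])
    confounder <- confounder + config$confounder_amplitudes[k] * sin(w + psi[k])
  }
  e <- sim_noise(n, config$noise_sd_exposure * config$noise_scale,
                 config$noise_model, config$ar1_coef)
  eps <- sim_noise(n, config$noise_sd_outcome * config$noise_scale,
                   config$noise_model, config$ar1_coef)
  x <- signal + e
  y <- config$beta_true * x + confounder + eps
  series <- daily_series(config$start_date + (t - 1L), outcome = y, exposure = x,
                         meta = list(sim_id = config$sim_id,
                                     sample_index = sample_index),
                         family = "gaussian")
  structure(list(series = series,
                 truth = list(beta_true = config$beta_true, signal = signal,
                              exposure_noise = e, confounder = confounder,
                              outcome_noise = eps)),
            class = "sim_sample")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.sim_sample <- function(x, ...) {
  m <- attr(x$series, "meta")
  cat(sprintf("sim_sample (sim %s, index %s): %d days, beta_true = %g\n",
              m$sim_id %||% "?", m$sample_index %||% "?", nrow(x$series),
              x$truth$beta_true))
  invisible(x)
}

#' Generate a reproducible study set
#'
#' `n_samples` independent samples whose per-sample seeds are derived
#' deterministically from `(config$seed, sample_index)`; regeneration with
#' the same config is bit-identical, and samples are independent of how many
#' of them are drawn.
#'
#' @param config a [sim_config()].
#' @param n_samples number of samples (>= 1).
#' @return A list of `sim_sample` objects.
#' @export
generate_study_set <- function(config, n_samples) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("n_samples must be a positive integer", call. = FALSE)
  lapply(seq_len(n_samples) - 1L, function(i) generate_sample(config, i))
}

#' Load externally published simulation samples
#'
#' Wraps a directory of CSV files -- for instance the simulation series
#' published alongside the original studies -- as `sim_sample` objects with
#' `beta_true = 1` and no latent decomposition, so the study harness can be
#' run on them exactly as on generated data.
#'
#' @param directory path containing `.csv` files.
#' @param mapping a [series_config()] describing the files' columns.
#' @param beta_true the slope the published series were generated with
#'   (default 1).
#' @return A list of `sim_sample` objects (empty, with a warning, if the
#'   directory holds no CSV files).
#' @export
load_published_samples <- function(directory, mapping = series_config(),
                                   beta_true = 1.0) {
  if (!dir.exists(directory)) stop("directory not found: ", directory, call. = FALSE)
  files <- sort(list.files(directory, pattern = "\\.csv$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) {
    warning("no CSV files in ", directory, call. = FALSE)
    return(list())
  }
  failures <- character(0)
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    s <- tryCatch(read_daily_csv(files[i], mapping, verbose = FALSE),
                  error = function(e) conditionMessage(e))
    if (is.character(s)) {
      failures <- c(failures, paste0(basename(files[i]), ": ", s))
    } else {
      attr(s, "meta")$sample_index <- i - 1L
      out[[i]] <- structure(list(series = s,
                                 truth = list(beta_true = beta_true,
                                              signal = NULL, exposure_noise = NULL,
                                              confounder = NULL, outcome_noise = NULL)),
                            class = "sim_sample")
    }
  }
  if (length(failures))
    stop("failed to load sample file(s):\n  ", paste(failures, collapse = "\n  "),
         call. = FALSE)
  out
}

#' Write a study set to disk
#'
#' One CSV per sample via [write_daily_csv()], plus a JSON manifest
#' recording the configuration and the derived per-sample seeds so a run
#' can be audited or regenerated.
#'
#' @param samples list of `sim_sample` objects.
#' @param directory output directory (created if needed).
#' @param config the [sim_config()] that produced the samples (stored in the
#'   manifest).
#' @return The manifest path, invisibly.
#' @export
write_study_set <- function(samples, directory, config = NULL) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(samples))
    write_daily_csv(samples[[i]]$series,
                    file.path(directory, sprintf("sample_%04d.csv", i - 1L)))
  manifest <- list(n_samples = length(samples),
                   files = sprintf("sample_%04d.csv", seq_along(samples) - 1L))
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$start_date <- format(cfg$start_date)
    manifest$config <- cfg
    manifest$sample_seeds <- vapply(seq_along(samples) - 1L,
                                    function(i) derive_seed(config$seed, i), 1L)
  }
  mpath <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mpath)
}
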