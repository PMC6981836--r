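# Shared fixtures: small stratified datasets built in code, plus the
# explicit-indicator oracle fits the conditional routines are checked against.

# A stratified_data not derived from a calendar: arbitrary grouping vector.
make_stratified <- function(x, y, g, dates = NULL) {
  ccwin:::fake_stratified(x, y, g, dates)
}

# Random small stratified dataset: S strata of 2..max_size days each.
random_stratified <- function(S, max_size = 5, family = "gaussian",
                              beta = 0.5, dow = FALSE) {
  sizes <- sample(2:max_size, S, replace = TRUE)
  g <- factor(rep(seq_len(S), sizes))
  n <- length(g)
  x <- rnorm(n)
  alpha <- rep(rnorm(S), sizes)
  if (family == "poisson") {
    y <- rpois(n, exp(beta * x + alpha))
  } else {
    y <- beta * x + alpha + rnorm(n)
  }
  ds <- make_stratified(x, y, g)
  if (dow) ds$dow <- factor(sample(ccwin:::dow_labels, n, replace = TRUE),
                            levels = ccwin:::dow_labels)
  ds
}

# Dummy-variable oracles: unconditional fits with one indicator per stratum.
oracle_poisson <- function(ds, with_dow = FALSE) {
  fm <- if (with_dow) outcome ~ exposure + dow + stratum else outcome ~ exposure + stratum
  glm(fm, data = as.data.frame(ds), family = poisson(),
      control = list(epsilon = 1e-13, maxit = 100))
}
oracle_gaussian <- function(ds, with_dow = FALSE) {
  fm <- if (with_dow) outcome ~ exposure + dow + stratum else outcome ~ exposure + stratum
  lm(fm, data = as.data.frame(ds))
}

write_sample_csv <- function(path, dates, outcome, exposure) {
  df <- data.frame(date = format(dates, "%Y-%m-%d"),
                   outcome = sprintf("%.17g", outcome),
                   exposure = sprintf("%.17g", exposure))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Poisson count series with seasonal confounding and known log-linear slope,
# for the epidemiological pipeline checks.
make_count_series <- function(n_days = 730, beta = 0.01, seed = 1,
                              conf_amp = 0.2, start = as.Date("2001-01-01")) {
  set.seed(seed)
  t <- seq_len(n_days)
  x <- 10 * sin(2 * pi * t / 183) + rnorm(n_days, sd = 5)
  season <- conf_amp * sin(2 * pi * t / 183 + pi / 3)
  mu <- exp(log(20) + beta * x + season)
  daily_series(start + t - 1L, outcome = rpois(n_days, mu), exposure = x,
               family = "poisson")
}
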