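# The module's central check: the conditional fits must coincide with
# unconditional fits carrying one explicit indicator per stratum.

test_that("conditional Poisson slope matches the dummy-variable GLM oracle", {
  set.seed(101)
  done <- 0
  while (done < 25) {
    ds <- random_stratified(S = sample(2:6, 1), family = "poisson")
    ds <- informative_strata(ds, "poisson")
    if (nrow(ds) == 0L || attr(ds, "n_strata") < 2L) next
    fit <- fit_conditional_poisson(ds, model_spec("poisson", dow_factor = FALSE))
    if (!fit$converged) next
    orc <- oracle_poisson(ds)
    expect_lt(abs(fit$beta - coef(orc)[["exposure"]]), 1e-6)
    expect_lt(abs(fit$se - sqrt(vcov(orc)["exposure", "exposure"])), 1e-6)
    done <- done + 1
  }
})

test_that("conditional Poisson agrees with the oracle when covariates are present", {
  set.seed(103)
  for (r in 1:5) {
    ds <- random_stratified(S = 6, max_size = 5, family = "poisson", dow = TRUE)
    ds <- informative_strata(ds, "poisson")
    fit <- suppressMessages(
      fit_conditional_poisson(ds, model_spec("poisson", dow_factor = TRUE)))
    if (!fit$converged) next
    orc <- oracle_poisson(ds, with_dow = TRUE)
    expect_lt(abs(fit$beta - coef(orc)[["exposure"]]), 1e-6)
  }
})

test_that("conditional Gaussian matches the dummy-variable OLS oracle to 1e-8", {
  set.seed(102)
  for (r in 1:25) {
    ds <- random_stratified(S = sample(2:6, 1), family = "gaussian")
    ds <- informative_strata(ds, "gaussian")
    fit <- fit_conditional_gaussian(ds, model_spec("gaussian", dow_factor = FALSE))
    orc <- oracle_gaussian(ds)
    expect_lt(abs(fit$beta - coef(orc)[["exposure"]]), 1e-8)
    expect_lt(abs(fit$se - sqrt(vcov(orc)["exposure", "exposure"])), 1e-8)
  }
})

test_that("balanced outcomes give a Poisson slope of exactly zero", {
  # equal counts within every pair: the conditional score vanishes at beta = 0
  x <- c(0, 1, 2, 5, -1, 3)
  y <- c(4, 4, 2, 2, 7, 7)
  ds <- make_stratified(x, y, factor(c(1, 1, 2, 2, 3, 3)))
  fit <- fit_conditional_poisson(ds, model_spec("poisson", dow_factor = FALSE))
  expect_identical(fit$beta, 0)
  expect_true(fit$converged)
})

test_that("monotone likelihood is reported as non-convergence with direction", {
  ds <- make_stratified(c(0, 1), c(0, 1), factor(c(1, 1)))
  fit <- fit_conditional_poisson(ds, model_spec("poisson", dow_factor = FALSE))
  expect_false(fit$converged)
  expect_match(fit$note, "\\+Inf")
})

test_that("exact linear response is recovered with zero residuals", {
  x <- c(1, 3, 2, 8, 0, 4)
  ds <- make_stratified(x, 2 * x, factor(c(1, 1, 2, 2, 3, 3)))
  fit <- fit_conditional_gaussian(ds, model_spec("gaussian", dow_factor = FALSE))
  expect_equal(fit$beta, 2, tolerance = 1e-12)
})

test_that("stratum-constant exposure shifts leave both families' slopes unchanged", {
  set.seed(104)
  dsg <- informative_strata(random_stratified(5, family = "gaussian"), "gaussian")
  dsp <- informative_strata(random_stratified(5, family = "poisson"), "poisson")
  shift <- function(ds) {
    ds$exposure <- ds$exposure + as.numeric(ds$stratum) * 13.7
    ds
  }
  f1 <- fit_conditional_gaussian(dsg, model_spec("gaussian", dow_factor = FALSE))
  f2 <- fit_conditional_gaussian(shift(dsg), model_spec("gaussian", dow_factor = FALSE))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)
  expect_equal(f1$se, f2$se, tolerance = 1e-9)
  p1 <- fit_conditional_poisson(dsp, model_spec("poisson", dow_factor = FALSE))
  p2 <- fit_conditional_poisson(shift(dsp), model_spec("poisson", dow_factor = FALSE))
  expect_equal(p1$beta, p2$beta, tolerance = 1e-6)
})

test_that("dropping uninformative strata changes neither beta nor the fitted likelihood", {
  set.seed(105)
  ds <- random_stratified(5, family = "poisson")
  # append a singleton and a flat-exposure pair
  extra_x <- c(1, 4, 4)
  extra_y <- c(2, 1, 3)
  aug <- make_stratified(c(ds$exposure, extra_x), c(ds$outcome, extra_y),
                         factor(c(as.character(ds$stratum), "s1", "flat", "flat")))
  spec <- model_spec("poisson", dow_factor = FALSE)
  f_aug <- fit_conditional_poisson(aug, spec)
  f_fil <- fit_conditional_poisson(informative_strata(aug, "poisson"), spec)
  expect_identical(f_aug$beta, f_fil$beta)
  expect_identical(f_aug$se, f_fil$se)
  expect_identical(f_aug$loglik, f_fil$loglik)
})

test_that("all-pairs 0/1 outcomes reduce to conditional logistic regression", {
  # pairs with one event each: the conditional likelihood is the matched-pair
  # logistic likelihood; maximize it independently in closed form
  x <- c(0.2, 1.1, -0.5, 0.3, 2.0, 0.7, 1.4, 0.1)
  y <- c(0, 1, 1, 0, 0, 1, 1, 0)
  g <- factor(rep(1:4, each = 2))
  ds <- make_stratified(x, y, g)
  pair_loglik <- function(b) {
    ll <- 0
    for (s in levels(g)) {
      xs <- x[g == s]; ys <- y[g == s]
      ll <- ll + b * xs[ys == 1] - log(exp(b * xs[1]) + exp(b * xs[2]))
    }
    ll
  }
  orc <- optimize(pair_loglik, c(-50, 50), maximum = TRUE, tol = 1e-10)
  fit <- fit_conditional_poisson(ds, model_spec("poisson", dow_factor = FALSE))
  expect_equal(fit$beta, orc$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik, orc$objective, tolerance = 1e-8)
})

test_that("within-stratum-constant covariates are dropped with a notice", {
  set.seed(106)
  ds <- random_stratified(6, family = "gaussian")
  ds$dow <- factor(ccwin:::dow_labels[as.integer(ds$stratum) %% 7 + 1],
                   levels = ccwin:::dow_labels)  # constant within each stratum
  expect_message(fit <- fit_conditional_gaussian(ds, model_spec("gaussian")),
                 "constant within every stratum")
  expect_true(any(grepl("dow", fit$dropped)))
  ref <- fit_conditional_gaussian(ds, model_spec("gaussian", dow_factor = FALSE))
  expect_equal(fit$beta, ref$beta)
})

test_that("natural spline basis satisfies boundary linearity and spans the truncated-power space", {
  # affine beyond the boundary knots: zero second differences outside
  grid <- seq(-5, 15, by = 0.1)
  B <- natural_spline_basis(grid, df = 4, boundary_knots = c(0, 10))
  out_lo <- grid < -0.2
  for (j in seq_len(ncol(B))) {
    d2 <- diff(B[out_lo, j], differences = 2)
    expect_lt(max(abs(d2)), 1e-8)
    d2hi <- diff(B[grid > 10.2, j], differences = 2)
    expect_lt(max(abs(d2hi)), 1e-8)
  }

  # df = 1: single monotone column
  b1 <- natural_spline_basis(seq(0, 10), df = 1)
  expect_identical(ncol(b1), 1L)
  expect_true(all(diff(b1[, 1]) > 0))

  # independent truncated-power natural-spline oracle with the same knots:
  # identical regression fits
  set.seed(107)
  v <- seq(0, 1, length.out = 120)
  df <- 5
  knots <- c(min(v), quantile(v, (1:(df - 1)) / df, names = FALSE), max(v))
  K <- length(knots)
  dk <- function(t, k) (pmax(t - knots[k], 0)^3 - pmax(t - knots[K], 0)^3) /
    (knots[K] - knots[k])
  TP <- cbind(v, sapply(seq_len(K - 2), function(k) dk(v, k) - dk(v, K - 1)))
  B2 <- natural_spline_basis(v, df = df)
  y <- sin(7 * v) + rnorm(length(v), sd = 0.1)
  expect_equal(fitted(lm(y ~ B2)), fitted(lm(y ~ TP)), tolerance = 1e-8)

  expect_error(natural_spline_basis(rep(1, 10), df = 3), "distinct")
})

test_that("time-series GLM recovers the slope without confounding and honours df/year", {
  set.seed(108)
  n <- 730
  x <- rnorm(n)
  y <- 1 * x + rnorm(n, sd = 0.3)
  s <- daily_series(as.Date("2001-01-01") + 0:(n - 1), y, x)
  f6 <- fit_time_series_glm(s, model_spec("gaussian"), df_per_year = 6)
  expect_lt(abs(f6$beta - 1), 3 * f6$se)
  f12 <- fit_time_series_glm(s, model_spec("gaussian"), df_per_year = 12)
  expect_false(identical(f6$beta, f12$beta))
  expect_identical(f12$method, "GLM12")
})

test_that("spline-GLM is attenuated on confounded data while the conditional fit is not", {
  cfg <- sim_config(2, seed = 11)
  sm <- generate_sample(cfg, 0)
  glm6 <- fit_time_series_glm(sm$series, model_spec("gaussian"), 6)
  cc2d <- fit_method(sm$series, "CC2D")
  expect_gt(abs(glm6$beta - 1), 0.3)
  expect_lt(abs(cc2d$beta - 1), 0.05)
})

test_that("fit results serialize to JSON and one-row CSV", {
  set.seed(109)
  ds <- informative_strata(random_stratified(4, family = "gaussian"), "gaussian")
  fit <- fit_conditional_gaussian(ds, model_spec("gaussian", dow_factor = FALSE))
  j <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(j$beta, fit$beta)
  expect_equal(j$ci_lo, unname(fit$ci95[1]))
  p <- withr::local_tempfile(fileext = ".csv")
  write_fit_csv(fit, p)
  row <- read.csv(p)
  expect_equal(row$beta, fit$beta, tolerance = 1e-12)
  expect_identical(nrow(row), 1L)
})
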