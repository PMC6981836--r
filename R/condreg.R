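#' Model specification for slope fits
#'
#' Describes the regression attached to a stratified dataset or a raw daily
#' series: the family, whether day-of-week enters as a factor covariate, and
#' an optional natural-spline adjustment for ambient temperature. The
#' exposure slope is always included -- it is the quantity of interest.
#'
#' Covariate terms that are constant within every stratum (for example the
#' day-of-week factor under schemes that already place each weekday in its
#' own stratum) cannot be identified by a conditional likelihood; they are
#' detected numerically and dropped with a notice.
#'
#' @param family `"gaussian"` or `"poisson"`.
#' @param dow_factor include day-of-week as a categorical adjustment
#'   (treatment contrasts, Monday reference). Default `TRUE`.
#' @param temperature_spline_df if non-`NULL`, adjust for temperature through
#'   a natural cubic spline with this many degrees of freedom (3 is the usual
#'   choice for daily mortality models).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("gaussian", "poisson"), dow_factor = TRUE,
                       temperature_spline_df = NULL) {
  family <- match.arg(family)
  if (!is.null(temperature_spline_df)) {
    temperature_spline_df <- as.integer(temperature_spline_df)
    if (is.na(temperature_spline_df) || temperature_spline_df < 1L)
      stop("temperature_spline_df must be a positive integer", call. = FALSE)
  }
  structure(list(family = family, dow_factor = isTRUE(dow_factor),
                 temperature_spline_df = temperature_spline_df),
            class = "model_spec")
}

#' Natural cubic spline basis
#'
#' An n-by-df natural cubic spline basis with boundary knots at the range of
#' the values, interior knots at equally spaced quantiles, and linear
#' extrapolation beyond the boundaries (second derivative zero at and beyond
#' the boundary knots). This is the standard smooth used both for the
#' temperature adjustment (3 df) and for the time trend of the classical
#' time-series comparator (df per year times years).
#'
#' @param values numeric vector with at least `df + 1` distinct points.
#' @param df number of basis columns, at least 1.
#' @param boundary_knots boundary knot positions (default the range of
#'   `values`); values beyond them are extrapolated linearly.
#' @return A numeric matrix with `length(values)` rows and `df` columns.
#' @export
natural_spline_basis <- function(values, df, boundary_knots = range(values, na.rm = TRUE)) {
  df <- as.integer(df)
  if (is.na(df) || df < 1L) stop("df must be a positive integer", call. = FALSE)
  if (length(unique(values[!is.na(values)])) < df + 1L)
    stop("need at least df + 1 distinct values for a ", df, "-df natural spline",
         call. = FALSE)
  inner <- values[values >= boundary_knots[1L] & values <= boundary_knots[2L]]
  knots <- if (df > 1L) stats::quantile(inner, (seq_len(df - 1L)) / df, names = FALSE)
  b <- splines::ns(values, knots = knots, Boundary.knots = boundary_knots)
  m <- matrix(as.numeric(b), nrow = length(values), ncol = df)
  colnames(m) <- paste0("ns", seq_len(df))
  m
}

# Design matrix (exposure first) for a stratified dataset.
build_design <- function(ds, spec) {
  X <- cbind(exposure = ds$exposure)
  dropped <- character(0)
  if (spec$dow_factor) {
    dw <- droplevels(ds$dow)
    if (nlevels(dw) > 1L) {
      D <- stats::model.matrix(~dw)[, -1L, drop = FALSE]
      colnames(D) <- paste0("dow", levels(dw)[-1L])
      X <- cbind(X, D)
    } else dropped <- c(dropped, "dow (single level)")
  }
  if (!is.null(spec$temperature_spline_df)) {
    if (!"temperature" %in% names(ds))
      stop("temperature_spline_df set but the series has no temperature", call. = FALSE)
    Tm <- natural_spline_basis(ds$temperature, spec$temperature_spline_df)
    colnames(Tm) <- paste0("temp_", colnames(Tm))
    X <- cbind(X, Tm)
  }
  # within-stratum centering; columns with no within-stratum variation are
  # unidentifiable under stratum elimination
  g <- ds$stratum
  Xc <- X - apply(X, 2L, function(col) stats::ave(col, g))
  scale <- apply(Xc, 2L, stats::sd)
  tol <- 1e-10 * pmax(apply(abs(X), 2L, max), 1)
  const <- scale < tol
  if (const["exposure"])
    stop("exposure has no within-stratum variation; slope not identifiable",
         call. = FALSE)
  if (any(const)) {
    dropped <- c(dropped, paste0(colnames(X)[const], " (constant within strata)"))
    message("dropping covariate(s) constant within every stratum: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    Xc <- Xc[, !const, drop = FALSE]
  }
  # remaining within-stratum collinearity: keep a full-rank pivot set,
  # exposure must survive
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) {
    keep <- sort(qx$pivot[seq_len(qx$rank)])
    if (!1L %in% keep)
      stop("exposure is collinear with retained covariates within all strata",
           call. = FALSE)
    dropped <- c(dropped, paste0(colnames(X)[-keep], " (collinear)"))
    X <- X[, keep, drop = FALSE]
    Xc <- Xc[, keep, drop = FALSE]
  }
  list(X = X, Xc = Xc, dropped = dropped)
}

new_cc_fit <- function(method, family, beta, se, coefficients, loglik,
                       n_strata_used, n_records_used, converged, n_iter,
                       dropped = character(0), removed = NULL, note = NULL) {
  structure(list(method = method, family = family, beta = beta, se = se,
                 ci95 = c(lower = beta - 1.96 * se, upper = beta + 1.96 * se),
                 coefficients = coefficients, loglik = loglik,
                 n_strata_used = n_strata_used, n_records_used = n_records_used,
                 converged = converged, n_iter = n_iter, dropped = dropped,
                 removed = removed, note = note),
            class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s family): beta = %.6g, se = %.6g, 95%% CI [%.6g, %.6g]\n",
              x$method, x$family, x$beta, x$se, x$ci95[1L], x$ci95[2L]))
  cat(sprintf("  records = %d, strata = %s, loglik = %.4f, converged = %s (%d iter)\n",
              x$n_records_used,
              if (is.na(x$n_strata_used)) "-" else x$n_strata_used,
              x$loglik, x$converged, x$n_iter))
  if (length(x$dropped)) cat("  dropped terms:", paste(x$dropped, collapse = "; "), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Serialize a fit result
#'
#' `fit_to_json()` returns a JSON string; `write_fit_csv()` writes the
#' one-row summary (method, beta, se, CI bounds, strata used, convergence)
#' used by the command-line interface.
#'
#' @param fit a `cc_fit`.
#' @param path output path for the CSV form.
#' @return JSON string, or `path` invisibly.
#' @export
fit_to_json <- function(fit) {
  stopifnot(inherits(fit, "cc_fit"))
  jsonlite::toJSON(list(
    method = fit$method, family = fit$family, beta = fit$beta, se = fit$se,
    ci_lo = unname(fit$ci95[1L]), ci_hi = unname(fit$ci95[2L]),
    loglik = fit$loglik, n_strata_used = fit$n_strata_used,
    n_records_used = fit$n_records_used, converged = fit$converged,
    n_iter = fit$n_iter, dropped = fit$dropped,
    coefficients = fit$coefficients), auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname fit_to_json
#' @export
write_fit_csv <- function(fit, path) {
  stopifnot(inherits(fit, "cc_fit"))
  utils::write.csv(data.frame(method = fit$method, beta = fit$beta, se = fit$se,
                              ci_lo = unname(fit$ci95[1L]),
                              ci_hi = unname(fit$ci95[2L]),
                              n_strata_used = fit$n_strata_used,
                              converged = fit$converged),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Conditional Poisson regression with stratum elimination
#'
#' Fits the slope of daily counts on exposure with one nuisance level per
#' stratum eliminated by conditioning on the stratum totals. Writing
#' eta_i = beta * x_i + covariate terms, the conditional log-likelihood is
#'
#'   sum_s ( sum_{i in s} y_i eta_i  -  Y_s log sum_{i in s} exp(eta_i) ),
#'
#' with Y_s the total count in stratum s: each stratum contributes a
#' multinomial term, and the per-stratum intercepts cancel. This is the
#' count-level equivalent of conditional logistic regression on matched
#' sets, and its maximiser coincides with the exposure coefficient of an
#' ordinary Poisson regression carrying one indicator per stratum.
#'
#' Maximisation is Newton-Raphson with analytic gradient and Hessian on
#' internally standardised columns, with step-halving on any likelihood
#' decrease; the log-likelihood is concave. Standard errors come from the
#' inverse observed information. A monotone likelihood (estimate escaping to
#' +/- infinity, as in a single pair with counts (0,1)) is reported as
#' `converged = FALSE` with a direction note.
#'
#' @param ds a `stratified_data` (uninformative strata are filtered
#'   internally, so pre-filtering with [informative_strata()] is optional
#'   and has no effect on the result).
#' @param spec a [model_spec()] with `family = "poisson"`.
#' @param max_iter,score_tol,step_tol optimizer controls.
#' @return A `cc_fit`.
#' @export
fit_conditional_poisson <- function(ds, spec = model_spec("poisson"),
                                    max_iter = 100L, score_tol = 1e-8,
                                    step_tol = 1e-10) {
  stopifnot(inherits(ds, "stratified_data"))
  if (spec$family != "poisson") stop("spec$family must be 'poisson'", call. = FALSE)
  if (any(ds$outcome < 0 | ds$outcome != round(ds$outcome)))
    stop("conditional Poisson regression needs non-negative integer outcomes",
         call. = FALSE)
  fds <- informative_strata(ds, "poisson")
  if (nrow(fds) == 0L) stop("no informative strata for the conditional fit", call. = FALSE)
  des <- build_design(fds, spec)
  X <- des$X
  p <- ncol(X)
  y <- fds$outcome
  g <- fds$stratum
  Ys <- as.numeric(rowsum(y, g))          # stratum totals, level order
  Yrec <- Ys[as.integer(g)]
  scale <- apply(des$Xc, 2L, stats::sd)
  Xs <- sweep(X, 2L, scale, "/")

  loglik_at <- function(th) {
    eta <- drop(Xs %*% th)
    lse <- log(rowsum(exp(eta - stats::ave(eta, g, FUN = max)), g)) +
      as.numeric(tapply(eta, g, max))
    sum(y * eta) - sum(Ys * lse)
  }
  score_hess <- function(th) {
    eta <- drop(Xs %*% th)
    mx <- stats::ave(eta, g, FUN = max)
    ez <- exp(eta - mx)
    denom <- as.numeric(rowsum(ez, g))[as.integer(g)]
    prob <- ez / denom
    w <- Yrec * prob
    grad <- drop(crossprod(Xs, y) - crossprod(Xs, w))
    M <- rowsum(prob * Xs, g)             # per-stratum mean of X under prob
    H <- -(crossprod(Xs, w * Xs) - crossprod(M, Ys * M))
    list(grad = grad, hess = (H + t(H)) / 2)
  }

  th <- rep(0, p)
  ll <- loglik_at(th)
  converged <- FALSE
  note <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sh <- score_hess(th)
    if (max(eigen(sh$hess, symmetric = TRUE, only.values = TRUE)$values) > 1e-6)
      stop("conditional Poisson Hessian not negative semidefinite", call. = FALSE)
    step <- tryCatch(solve(sh$hess, -sh$grad), error = function(e) NULL)
    if (is.null(step))
      stop("singular information: exposure collinear with retained covariates ",
           "within all strata", call. = FALSE)
    # step-halving if the likelihood would decrease
    lam <- 1
    repeat {
      ll_new <- loglik_at(th + lam * step)
      if (ll_new >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    th <- th + lam * step
    ll <- ll_new
    if (max(abs(sh$grad)) < score_tol || max(abs(lam * step)) < step_tol) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(th)) > 10) {                # monotone likelihood: estimate escaping
    converged <- FALSE
    j <- which.max(abs(th))
    note <- sprintf("estimate for '%s' diverging to %sInf (monotone likelihood)",
                    colnames(X)[j], if (th[j] > 0) "+" else "-")
  }
  sh <- score_hess(th)
  V <- tryCatch(solve(-sh$hess), error = function(e) matrix(NA_real_, p, p))
  beta_hat <- th / scale
  se_hat <- sqrt(diag(V)) / scale
  coefs <- data.frame(term = colnames(X), estimate = beta_hat, se = se_hat,
                      row.names = NULL)
  new_cc_fit(method = attr(ds, "scheme")$name, family = "poisson",
             beta = unname(beta_hat[1L]), se = unname(se_hat[1L]),
             coefficients = coefs, loglik = ll,
             n_strata_used = nlevels(g), n_records_used = nrow(fds),
             converged = converged, n_iter = iter, dropped = des$dropped,
             removed = attr(fds, "removed"), note = note)
}

#' Conditional Gaussian (within-stratum least squares) fit
#'
#' The continuous-response analogue of the conditional Poisson fit: least
#' squares with one intercept per stratum, computed by centering the
#' response and all regressors within each stratum and running ordinary
#' least squares on the centered data (Frisch-Waugh). The residual degrees
#' of freedom are `n_records - n_strata - n_slope_parameters` and the
#' standard errors use that df, exactly as if the stratum indicators had
#' been estimated explicitly.
#'
#' @inheritParams fit_conditional_poisson
#' @param spec a [model_spec()] with `family = "gaussian"`.
#' @return A `cc_fit`.
#' @export
fit_conditional_gaussian <- function(ds, spec = model_spec("gaussian")) {
  stopifnot(inherits(ds, "stratified_data"))
  if (spec$family != "gaussian") stop("spec$family must be 'gaussian'", call. = FALSE)
  fds <- informative_strata(ds, "gaussian")
  if (nrow(fds) == 0L) stop("no informative strata for the conditional fit", call. = FALSE)
  des <- build_design(fds, spec)
  Xc <- des$Xc
  g <- fds$stratum
  yc <- fds$outcome - stats::ave(fds$outcome, g)
  n <- nrow(fds)
  S <- nlevels(g)
  p <- ncol(Xc)
  df <- n - S - p
  if (df <= 0L) stop("zero residual degrees of freedom", call. = FALSE)
  XtX <- crossprod(Xc)
  th <- drop(solve(XtX, crossprod(Xc, yc)))
  res <- yc - drop(Xc %*% th)
  rss <- sum(res^2)
  sigma2 <- rss / df
  V <- sigma2 * solve(XtX)
  se <- sqrt(diag(V))
  # gaussian log-likelihood at the MLE variance (stratum intercepts profiled)
  ll <- if (rss > 0) -n / 2 * (log(2 * pi * rss / n) + 1) else Inf
  coefs <- data.frame(term = colnames(des$X), estimate = th, se = se,
                      row.names = NULL)
  new_cc_fit(method = attr(ds, "scheme")$name, family = "gaussian",
             beta = unname(th[1L]), se = unname(se[1L]), coefficients = coefs,
             loglik = ll, n_strata_used = S, n_records_used = n,
             converged = TRUE, n_iter = 1L, dropped = des$dropped,
             removed = attr(fds, "removed"))
}

#' Classical spline-adjusted time-series GLM comparator
#'
#' The conventional alternative to the case-crossover fits: an unconditional
#' regression of the outcome on exposure, a day-of-week factor, and a
#' natural cubic spline of the day index with `round(df_per_year * years)`
#' degrees of freedom (6 df/year is the common default; 12 df/year is a
#' stricter variant). With seasonal confounding concentrated at periods the
#' spline cannot resolve, this estimator's slope can be badly biased -- the
#' failure mode the short-window conditional designs avoid.
#'
#' @param series a [daily_series] (rows with missing outcome or exposure are
#'   dropped).
#' @param spec a [model_spec()]; its family selects Gaussian or Poisson
#'   regression and its temperature spline is honoured.
#' @param df_per_year degrees of freedom per year for the time spline.
#' @return A `cc_fit` with method `"GLM<df_per_year>"`.
#' @export
fit_time_series_glm <- function(series, spec = model_spec("gaussian"),
                                df_per_year = 6) {
  stopifnot(inherits(series, "daily_series"))
  keep <- !is.na(series$outcome) & !is.na(series$exposure)
  dat <- as.data.frame(series)[keep, , drop = FALSE]
  n <- nrow(dat)
  if (n < 3L) stop("too few complete rows for a time-series fit", call. = FALSE)
  dayidx <- as.numeric(dat$date - series$date[1L])
  years_span <- (max(dayidx) - min(dayidx) + 1) / 365.25
  df_time <- as.integer(round(df_per_year * years_span))
  if (df_time < 1L) stop("df_per_year x years span must be at least 1", call. = FALSE)
  X <- cbind(exposure = dat$exposure)
  if (spec$dow_factor) {
    dw <- factor(dow_labels[day_of_week(dat$date)], levels = dow_labels)
    dw <- droplevels(dw)
    if (nlevels(dw) > 1L) {
      D <- stats::model.matrix(~dw)[, -1L, drop = FALSE]
      colnames(D) <- paste0("dow", levels(dw)[-1L])
      X <- cbind(X, D)
    }
  }
  if (!is.null(spec$temperature_spline_df)) {
    if (!"temperature" %in% names(dat))
      stop("temperature_spline_df set but the series has no temperature", call. = FALSE)
    Tm <- natural_spline_basis(dat$temperature, spec$temperature_spline_df)
    colnames(Tm) <- paste0("temp_", colnames(Tm))
    X <- cbind(X, Tm)
  }
  Tt <- natural_spline_basis(dayidx, df_time)
  colnames(Tt) <- paste0("time_", colnames(Tt))
  X <- cbind(X, Tt)
  fam <- if (spec$family == "poisson") stats::poisson() else stats::gaussian()
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, X), dat$outcome, family = fam)
  cf <- fit$coefficients
  if (any(is.na(cf))) {
    if (is.na(cf["exposure"]))
      stop("design matrix rank-deficient: exposure not identifiable", call. = FALSE)
    stop("design matrix rank-deficient", call. = FALSE)
  }
  # dispersion: 1 for poisson; residual MSE for gaussian
  Rmat <- qr.R(fit$qr)
  Vu <- chol2inv(Rmat)
  phi <- if (spec$family == "gaussian")
    sum(fit$residuals^2 * fit$weights) / fit$df.residual else 1
  se_all <- sqrt(phi * diag(Vu))[order(fit$qr$pivot)]
  names(se_all) <- names(cf)
  ll <- if (spec$family == "poisson")
    sum(stats::dpois(dat$outcome, fit$fitted.values, log = TRUE))
  else -n / 2 * (log(2 * pi * sum(fit$residuals^2) / n) + 1)
  coefs <- data.frame(term = names(cf), estimate = unname(cf), se = unname(se_all),
                      row.names = NULL)
  new_cc_fit(method = paste0("GLM", format(df_per_year)), family = spec$family,
             beta = unname(cf["exposure"]), se = unname(se_all["exposure"]),
             coefficients = coefs, loglik = ll, n_strata_used = NA_integer_,
             n_records_used = n, converged = fit$converged %||% TRUE,
             n_iter = fit$iter %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
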