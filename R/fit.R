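#' Goodness-of-fit statistics
#'
#' Computes the coefficient of determination \eqn{R^2 = 1 - SSE/SS_{tot}} and
#' the associated F statistic \eqn{F = (R^2/df_1) / ((1-R^2)/df_2)} with
#' \eqn{df_1} = number of non-constant parameters and
#' \eqn{df_2 = n - df_1 - 1}, plus the upper-tail p-value from the F
#' distribution. This is the statistic reported for every fitted curve,
#' linear or nonlinear, so all candidate forms share one table layout.
#'
#' @param observed,fitted numeric vectors of equal length.
#' @param n_terms number of non-constant parameters of the fitted curve
#'   (`df1`).
#' @return list with `r2`, `f_value`, `df1`, `df2`, `p_value`.
#' @examples
#' goodness_of_fit(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8), n_terms = 1)
#' @export
goodness_of_fit <- function(observed, fitted, n_terms) {
  observed <- as.numeric(observed); fitted <- as.numeric(fitted)
  n <- length(observed)
  if (length(fitted) != n) stop_sg("observed and fitted lengths differ")
  if (n <= n_terms + 1L) stop_sg("need n > n_terms + 1")
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0) stop_sg("observed values are constant; R^2 undefined")
  sse <- sum((observed - fitted)^2)
  r2 <- 1 - sse / sstot
  df1 <- as.integer(n_terms)
  df2 <- as.integer(n - n_terms - 1L)
  f <- if (r2 >= 1) Inf else max(0, (r2 / df1) / ((1 - r2) / df2))
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  list(r2 = r2, f_value = f, df1 = df1, df2 = df2, p_value = p)
}

new_growth_fit <- function(form, params, gof, n, converged, fit_scale,
                           fitted, data, flags = character()) {
  # adj_r2 penalizes parameter count so nested forms compare fairly
  adj <- if (is.finite(gof$r2) && n - form$n_par > 0)
    1 - (1 - gof$r2) * (n - 1) / (n - form$n_par) else NA_real_
  structure(list(
    form = form, params = stats::setNames(as.numeric(params), form$par_names),
    r2 = gof$r2, adj_r2 = adj, f_value = gof$f_value, df1 = gof$df1,
    df2 = gof$df2, p_value = gof$p_value, n = as.integer(n),
    converged = converged, fit_scale = fit_scale, fitted = fitted,
    data = data, flags = flags
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s (%s scale)%s\n", x$form$form_id, x$fit_scale,
              if (!x$converged) " [not converged]" else ""))
  cat("  ", equation_text(x$form, x$params), "\n", sep = "")
  cat(sprintf("  R2 = %.4f  F(%d, %d) = %.3f  p = %.3g  n = %d\n",
              x$r2, x$df1, x$df2, x$f_value, x$p_value, x$n))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$params

#' Predict from a fitted growth curve
#'
#' Predictions are always on the original response scale (metres or
#' centimetres), regardless of the scale the curve was fitted on: forms
#' fitted by least squares on \eqn{\ln y} are exponentiated back.
#'
#' @param object a `growth_fit`.
#' @param x numeric vector of primary-predictor values.
#' @param covariates covariate matrix/data.frame for multivariate forms.
#' @param ... unused.
#' @export
predict.growth_fit <- function(object, x, covariates = NULL, ...) {
  form_predict(object$form, object$params, x, covariates)
}

#' Serialize a fitted curve to JSON
#'
#' @param fit a `growth_fit`.
#' @return a JSON string with the form id, fitting scale, parameters and
#'   goodness-of-fit statistics.
#' @export
fit_to_json <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  jsonlite::toJSON(list(
    form_id = fit$form$form_id, covariates = fit$form$covariates,
    scale = fit$fit_scale, params = as.list(fit$params), r2 = fit$r2,
    f = fit$f_value, df1 = fit$df1, df2 = fit$df2, p = fit$p_value,
    n = fit$n, converged = fit$converged), auto_unbox = TRUE, digits = NA)
}

# Transformed design matrix + response for the linearizable basic forms.
linearized_design <- function(form_id, x, y) {
  switch(form_id,
    linear      = list(X = cbind(1, x),            y = y, scale = "original"),
    logarithmic = list(X = cbind(1, log(x)),       y = y, scale = "original"),
    reciprocal  = list(X = cbind(1, 1 / x),        y = y, scale = "original"),
    quadratic   = list(X = cbind(1, x, x^2),       y = y, scale = "original"),
    cubic       = list(X = cbind(1, x, x^2, x^3),  y = y, scale = "original"),
    s_curve     = list(X = cbind(1, 1 / x),        y = log(y), scale = "log"),
    growth      = list(X = cbind(1, x),            y = log(y), scale = "log"),
    stop_sg(sprintf("form '%s' is not linearizable", form_id)))
}

#' Fit a linearizable basic form by ordinary least squares
#'
#' The polynomial and transform curves are fitted on their linearizing
#' design (`x`, `ln x`, `1/x`, powers of `x`); the `s_curve` and `growth`
#' forms are fitted as OLS of \eqn{\ln y} on \eqn{1/x} and \eqn{x}
#' respectively — the convention of classical curve-estimation software.
#' Reported \eqn{R^2}/F/p are computed on the fitting scale, recorded in
#' `fit_scale`.
#'
#' @param form a basic, non-logistic [growth_form()], or its id string.
#' @param x,y numeric predictor and response vectors.
#' @return a `growth_fit`.
#' @examples
#' x <- c(5, 10, 20, 40)
#' fit_closed_form("s_curve", x, exp(3.174 - 8.341 / x))
#' @export
fit_closed_form <- function(form, x, y) {
  if (is.character(form)) form <- growth_form(form)
  stopifnot(inherits(form, "growth_form"))
  if (!form$linearizable)
    stop_sg(sprintf("form '%s' has no closed-form fit; use fit_nls()",
                    form$form_id))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_sg("x and y lengths differ")
  if (n <= form$n_par) stop_sg("need more observations than parameters")
  if (form$form_id %in% c("logarithmic", "reciprocal", "s_curve") &&
      any(x <= 0))
    stop_sg(sprintf("form '%s' requires x > 0", form$form_id))
  if (form$fit_scale == "log" && any(y <= 0))
    stop_sg(sprintf("form '%s' needs y > 0 (log transform); offending rows: %s",
                    form$form_id,
                    paste(utils::head(which(y <= 0), 10), collapse = ", ")))
  d <- linearized_design(form$form_id, x, y)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) stop_sg("singular design matrix")
  beta <- qr.coef(qrX, d$y)
  fitted <- drop(d$X %*% beta)
  gof <- goodness_of_fit(d$y, fitted, n_terms = form$n_par - 1L)
  new_growth_fit(form, beta, gof, n, converged = TRUE, fit_scale = d$scale,
                 fitted = fitted, data = list(x = x, y = y))
}

#' Starting values for nonlinear fitting
#'
#' Auto-initialization used by [fit_nls()]: logistic starts at
#' `b1 = 1.05 * max(y)`, `b3 = median(x)` and `b2` from the slope of the
#' logit linearization \eqn{\ln(b_1/y - 1)} on `x`; every other nonlinear
#' form starts from its closed-form transform fit; multivariate forms start
#' from the basic-form start with all covariate coefficients at zero.
#'
#' @param form a [growth_form()].
#' @param x,y numeric predictor and response vectors.
#' @return named numeric vector of length `form$n_par`.
#' @export
default_init <- function(form, x, y) {
  stopifnot(inherits(form, "growth_form"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(y) < form$n_par + 1L) stop_sg("too few observations for a start")
  base <- if (form$form_id == "logistic") {
    if (max(y) <= 0) stop_sg("logistic start needs max(y) > 0")
    b1 <- 1.05 * max(y)
    b3 <- stats::median(x)
    w <- pmin(pmax(y, 1e-8), b1 * (1 - 1e-8))
    lg <- log(b1 / w - 1)
    sl <- stats::cov(x, lg) / stats::var(x)
    b2 <- if (is.finite(sl) && sl != 0) -sl else 0.1
    c(b1, b2, b3)
  } else {
    unname(coef(fit_closed_form(growth_form(form$form_id), x, y)))
  }
  stats::setNames(c(base, rep(0, form$n_covariates)), form$par_names)
}

#' Fit any growth-curve form by nonlinear least squares
#'
#' Minimizes the residual sum of squares on the original response scale with
#' a Levenberg–Marquardt trust-region backend (numeric Jacobian). Works for
#' the logistic form and all multivariate extensions, and can re-fit the
#' linearizable forms on the original scale. Parameter points where a
#' prediction is non-finite or a logistic denominator is non-positive are
#' penalized with a large residual instead of crashing the solver. On
#' non-convergence the best-so-far fit is returned with `converged = FALSE`
#' after `restarts` seeded, jittered retries keeping the lowest SSE.
#'
#' @param form a [growth_form()] or form id string.
#' @param x,y numeric predictor and response.
#' @param covariates covariate matrix for multivariate forms.
#' @param init `"auto"` (see [default_init()]) or a numeric start vector.
#' @param tol convergence tolerance on relative cost decrease.
#' @param max_iter iteration cap per start.
#' @param restarts jittered restarts attempted if the first run fails to
#'   converge.
#' @param seed seed for the restart jitter (only source of randomness).
#' @return a `growth_fit` with `fit_scale = "original"`.
#' @examples
#' x <- seq(2, 40, length.out = 60)
#' y <- 19.835 / (1 + exp(-0.205 * (x - 16.246)))
#' fit_nls("logistic", x, y)
#' @export
fit_nls <- function(form, x, y, covariates = NULL, init = "auto",
                    tol = 1e-10, max_iter = 500L, restarts = 3L, seed = 1L) {
  if (is.character(form)) form <- growth_form(form)
  stopifnot(inherits(form, "growth_form"))
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_sg("x and y lengths differ")
  if (n - form$n_par <= 0L) stop_sg("no residual degrees of freedom")
  Z <- if (form$n_covariates > 0) as.matrix(covariates) else NULL
  start <- if (identical(init, "auto")) default_init_xy(form, x, y)
           else stats::setNames(as.numeric(init), form$par_names)
  if (any(!is.finite(start))) stop_sg("non-finite starting values")

  penalty <- 1e6 * (1 + max(abs(y)))
  resid_fun <- function(par) {
    pred <- eval_form_guarded(form, par, x, Z)
    r <- y - pred
    bad <- !is.finite(r)
    if (any(bad)) r[bad] <- penalty
    r
  }
  run <- function(par0) {
    out <- try(minpack.lm::nls.lm(
      par = par0, fn = resid_fun,
      control = minpack.lm::nls.lm.control(
        ftol = tol, ptol = tol, maxiter = min(as.integer(max_iter), 1024L),
        maxfev = 100L * (form$n_par + 1L) * 10L)), silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    # info 1-3: ftol/ptol convergence; 4: zero gradient (exact solution)
    list(par = out$par, sse = sum(resid_fun(out$par)^2),
         converged = out$info %in% 1:4)
  }
  best <- run(start)
  if (is.null(best) || !best$converged) {
    jit <- with_seed(seed, lapply(seq_len(restarts), function(i)
      start * (1 + 0.1 * stats::rnorm(length(start))) +
        0.01 * stats::rnorm(length(start))))
    for (s in jit) {
      cand <- run(s)
      if (is.null(cand)) next
      if (is.null(best) || cand$sse < best$sse ||
          (cand$converged && !best$converged && cand$sse <= best$sse * (1 + 1e-6)))
        best <- cand
    }
  }
  if (is.null(best)) stop_sg("nonlinear fit failed from every start")
  pars <- as.numeric(best$par)
  fitted <- eval_form_guarded(form, pars, x, Z)
  fitted[!is.finite(fitted)] <- mean(y)   # degenerate points: null prediction
  gof <- tryCatch(goodness_of_fit(y, fitted, n_terms = form$n_par - 1L),
                  error = function(e) list(r2 = NA_real_, f_value = NA_real_,
                                           df1 = form$n_par - 1L,
                                           df2 = n - form$n_par,
                                           p_value = NA_real_))
  flags <- check_params(form, pars)
  new_growth_fit(form, pars, gof, n, converged = isTRUE(best$converged),
                 fit_scale = "original", fitted = fitted,
                 data = list(x = x, y = y, covariates = Z), flags = flags)
}

# default_init on raw vectors (keeps fit_nls free of inventory plumbing).
default_init_xy <- function(form, x, y) default_init(form, x, y)

# Evaluation without the user-facing validation/warnings; logistic
# denominators <= 0 are mapped to NaN so the fitter penalizes them.
eval_form_guarded <- function(form, params, x, Z) {
  z <- if (form$n_covariates > 0)
    drop(Z %*% params[seq.int(form$n_par - form$n_covariates + 1L, form$n_par)])
  else 0
  if (form$form_id == "logistic") {
    denom <- 1 + exp(-params[2] * (x - params[3])) + z
    out <- params[1] / denom
    out[denom <= 0] <- NaN
    out
  } else {
    eval_form_core(form$form_id, params, x, z, form$n_base_params)
  }
}
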