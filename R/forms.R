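#' Growth-curve form catalogue
#'
#' The package works with eight classical growth-curve forms, each available
#' as a basic single-predictor curve or as a multivariate extension that
#' appends additive environmental-covariate terms:
#'
#' \describe{
#'   \item{linear}{\eqn{y = b_0 + b_1 x}}
#'   \item{logarithmic}{\eqn{y = b_0 + b_1 \ln x}}
#'   \item{reciprocal}{\eqn{y = b_0 + b_1 / x}}
#'   \item{quadratic}{\eqn{y = b_0 + b_1 x + b_2 x^2}}
#'   \item{cubic}{\eqn{y = b_0 + b_1 x + b_2 x^2 + b_3 x^3}}
#'   \item{s_curve}{\eqn{y = \exp(b_0 + b_1 / x)}; saturating with asymptote
#'     \eqn{\exp(b_0)} when \eqn{b_1 < 0}}
#'   \item{growth}{\eqn{y = \exp(b_0 + b_1 x)}, a simple exponential trend}
#'   \item{logistic}{\eqn{y = b_1 / (1 + \exp(-b_2 (x - b_3)))}; asymptote
#'     \eqn{b_1}, inflection at \eqn{x = b_3}}
#' }
#'
#' Multivariate extensions add covariate terms where the curve is linear in
#' its parameters: inside the exponent for `s_curve`/`growth`, inside the
#' denominator for `logistic`, and additively on the response for the
#' polynomial/transform forms. Setting every covariate coefficient to zero
#' recovers the basic curve exactly.
#'
#' @param form_id one of `form_ids()`.
#' @param covariates character vector of covariate names to append (empty for
#'   a basic form).
#' @return an object of class `growth_form`: a list with the form id, its
#'   parameter names, covariate names, parameter count, whether it is
#'   linearizable by a variable transform, and the scale (`"original"` or
#'   `"log"`) on which the linearizing transform operates.
#' @examples
#' f <- growth_form("logistic")
#' form_predict(f, c(b1 = 19.835, b2 = 0.205, b3 = 16.246), x = 16.246)
#' @export
growth_form <- function(form_id, covariates = character()) {
  form_id <- match.arg(form_id, form_ids())
  covariates <- as.character(covariates)
  n_base <- switch(form_id,
    linear = 2L, logarithmic = 2L, reciprocal = 2L,
    quadratic = 3L, cubic = 4L, s_curve = 2L, growth = 2L, logistic = 3L)
  k <- length(covariates)
  base_names <- if (form_id == "logistic") c("b1", "b2", "b3")
                else paste0("b", seq_len(n_base) - 1L)
  cov_start <- if (form_id == "logistic") 4L else n_base
  par_names <- c(base_names,
                 if (k > 0) paste0("b", seq.int(cov_start, cov_start + k - 1L)))
  structure(list(
    form_id = form_id,
    family = if (k > 0) "multivariate" else "basic",
    covariates = covariates,
    n_covariates = k,
    n_base_params = n_base,
    n_par = n_base + k,
    par_names = par_names,
    linearizable = form_id != "logistic" && k == 0L,
    fit_scale = if (form_id %in% c("s_curve", "growth")) "log" else "original"
  ), class = "growth_form")
}

#' @describeIn growth_form the eight form identifiers, in catalogue order
#'   (the order used for tie-breaking during model selection).
#' @export
form_ids <- function() {
  c("linear", "logarithmic", "reciprocal", "quadratic", "cubic",
    "s_curve", "growth", "logistic")
}

#' @export
print.growth_form <- function(x, ...) {
  cat(sprintf("<growth_form> %s (%s), %d parameter(s)\n",
              x$form_id, x$family, x$n_par))
  cat("  ", equation_text(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a growth-curve form
#'
#' Computes the curve value at the given predictors, exactly as the formula
#' is written (see [growth_form()]). Non-finite results (overflowing
#' exponents, vanishing logistic denominators) are returned as-is with a
#' warning rather than raising an error.
#'
#' @param form a [growth_form()].
#' @param params numeric vector matching `form$n_par` (order: base
#'   parameters, then one coefficient per covariate).
#' @param x numeric vector, the primary predictor (DBH or stand age). Must be
#'   strictly positive for forms containing `1/x` or `ln x`.
#' @param covariates numeric matrix (or data.frame) with one column per
#'   covariate of the form, in the form's covariate order. Ignored for basic
#'   forms.
#' @return numeric vector of predictions, same length as `x`.
#' @export
form_predict <- function(form, params, x, covariates = NULL) {
  stopifnot(inherits(form, "growth_form"))
  params <- as.numeric(params)
  if (length(params) != form$n_par)
    stop_sg(sprintf("form '%s' needs %d parameters, got %d",
                    form$form_id, form$n_par, length(params)))
  x <- as.numeric(x)
  if (form$form_id %in% c("logarithmic", "reciprocal", "s_curve") &&
      any(x <= 0))
    stop_sg(sprintf("form '%s' requires x > 0", form$form_id))
  z <- cov_term(form, params, covariates, length(x))
  y <- eval_form_core(form$form_id, params, x, z, form$n_base_params)
  if (any(!is.finite(y)))
    warning(sprintf("form '%s' produced non-finite values", form$form_id),
            call. = FALSE)
  check_params(form, params, warn = TRUE)
  y
}

# Additive covariate contribution (0 for basic forms).
cov_term <- function(form, params, covariates, n) {
  k <- form$n_covariates
  if (k == 0L) return(0)
  if (is.null(covariates))
    stop_sg("multivariate form needs covariate values")
  Z <- as.matrix(covariates)
  if (ncol(Z) != k)
    stop_sg(sprintf("expected %d covariate column(s), got %d", k, ncol(Z)))
  if (nrow(Z) != n) stop_sg("covariate rows must match length(x)")
  drop(Z %*% params[seq.int(form$n_par - k + 1L, form$n_par)])
}

# Raw formula evaluation; no validation (shared by predict and fitters).
eval_form_core <- function(form_id, params, x, z, n_base) {
  b <- params
  switch(form_id,
    linear      = b[1] + b[2] * x + z,
    logarithmic = b[1] + b[2] * log(x) + z,
    reciprocal  = b[1] + b[2] / x + z,
    quadratic   = b[1] + b[2] * x + b[3] * x^2 + z,
    cubic       = b[1] + b[2] * x + b[3] * x^2 + b[4] * x^3 + z,
    s_curve     = exp(b[1] + b[2] / x + z),
    growth      = exp(b[1] + b[2] * x + z),
    logistic    = b[1] / (1 + exp(-b[2] * (x - b[3])) + z))
}

# Parameter sanity flags (logistic needs a positive asymptote and b2 != 0 for
# a proper sigmoid). Returns character vector of flags, optionally warning.
check_params <- function(form, params, warn = FALSE) {
  flags <- character()
  if (form$form_id == "logistic") {
    if (params[1] <= 0) flags <- c(flags, "logistic asymptote b1 <= 0")
    if (params[2] == 0) flags <- c(flags, "logistic slope b2 == 0 (no sigmoid)")
  }
  if (warn && length(flags))
    warning(paste(flags, collapse = "; "), call. = FALSE)
  flags
}

#' Human-readable equation for a form
#'
#' @param form a [growth_form()].
#' @param params optional numeric parameters; if omitted, symbolic names are
#'   printed.
#' @return a single string such as `"y = exp(3.174 - 8.341/x)"`.
#' @export
equation_text <- function(form, params = NULL) {
  nm <- if (is.null(params)) form$par_names
        else formatC(params, digits = 4, format = "g")
  k <- form$n_covariates
  xs <- if (k > 0) "x1" else "x"
  covs <- if (k > 0) {
    idx <- seq.int(form$n_par - k + 1L, form$n_par)
    paste0(vapply(seq_len(k), function(j)
      paste0(" + ", nm[idx[j]], "*x", j + 1L), ""), collapse = "")
  } else ""
  body <- switch(form$form_id,
    linear      = paste0(nm[1], " + ", nm[2], "*", xs, covs),
    logarithmic = paste0(nm[1], " + ", nm[2], "*ln(", xs, ")", covs),
    reciprocal  = paste0(nm[1], " + ", nm[2], "/", xs, covs),
    quadratic   = paste0(nm[1], " + ", nm[2], "*", xs, " + ", nm[3], "*", xs,
                         "^2", covs),
    cubic       = paste0(nm[1], " + ", nm[2], "*", xs, " + ", nm[3], "*", xs,
                         "^2 + ", nm[4], "*", xs, "^3", covs),
    s_curve     = paste0("exp(", nm[1], " + ", nm[2], "/", xs, covs, ")"),
    growth      = paste0("exp(", nm[1], " + ", nm[2], "*", xs, covs, ")"),
    logistic    = paste0(nm[1], " / (1 + exp(-", nm[2], "*(", xs, " - ",
                         nm[3], "))", covs, ")"))
  paste0("y = ", body)
}
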