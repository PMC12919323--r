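# Per-species analysis: candidate fitting, model selection, covariate
# extension, hold-out validation and report tables.

relation_ids <- function() c("dbh_height", "age_dbh")

relation_xy <- function(table, relation) {
  relation <- match.arg(relation, relation_ids())
  if (relation == "dbh_height") list(x = table$dbh, y = table$height)
  else list(x = table$age, y = table$dbh)
}

species_rows <- function(table, species) {
  tolower(trimws(table$species)) == tolower(trimws(species))
}

#' Fit all candidate curve forms for one species and relation
#'
#' Fits each requested basic form on the species' records: linearizable
#' forms by [fit_closed_form()] (the curve-estimation convention) and the
#' logistic by [fit_nls()]. A form that fails (e.g. too few degrees of
#' freedom for the cubic) is recorded as an error entry without aborting the
#' batch.
#'
#' @param table inventory `data.frame` (typically the modelling partition).
#' @param species species label, matched case-insensitively; `NULL` uses all
#'   rows.
#' @param relation `"dbh_height"` (predictor DBH, response height) or
#'   `"age_dbh"` (predictor stand age, response DBH).
#' @param forms form ids to fit (default all eight).
#' @param refit_nls if `TRUE`, linearizable forms are additionally re-fitted
#'   on the original response scale by [fit_nls()] and the NLS fit is kept.
#'   Default `FALSE` (report transformed-scale fits, tagged via `fit_scale`).
#' @return list of `growth_fit` (or `growth_fit_error`) objects, one per
#'   form, in catalogue order; class `growth_fit_list`.
#' @export
fit_candidates <- function(table, species = NULL, relation, forms = form_ids(),
                           refit_nls = FALSE) {
  sub <- if (is.null(species)) table
         else table[species_rows(table, species), , drop = FALSE]
  if (nrow(sub) == 0L)
    stop_sg(sprintf("no records for species '%s'", species))
  d <- relation_xy(sub, relation)
  fits <- lapply(forms, function(id) {
    f <- growth_form(id)
    res <- tryCatch({
      if (!f$linearizable) fit_nls(f, d$x, d$y)
      else if (refit_nls) fit_nls(f, d$x, d$y)
      else fit_closed_form(f, d$x, d$y)
    }, error = function(e) {
      structure(list(form_id = id, message = conditionMessage(e)),
                class = "growth_fit_error")
    })
    res
  })
  names(fits) <- forms
  structure(fits, class = "growth_fit_list",
            species = species, relation = relation, n = nrow(sub))
}

#' Select the best fit by coefficient of determination
#'
#' Keeps converged fits only and returns the one with the largest
#' coefficient of determination; ties (within 1e-12) go to the fit with
#' fewer parameters, then to catalogue order. By default the ranking uses
#' the degrees-of-freedom-adjusted \eqn{R^2}
#' (\eqn{1 - (1 - R^2)(n-1)/(n-k)} for a `k`-parameter curve), which lets a
#' parsimonious true form beat a flexible polynomial that merely fits
#' noise; `statistic = "r2"` ranks by the plain statistic instead. Values
#' are compared as reported on each fit's own fitting scale.
#'
#' @param fits a list of `growth_fit` objects (error entries are skipped).
#' @param statistic `"adj_r2"` (default) or `"r2"`.
#' @return the winning `growth_fit`.
#' @export
select_best <- function(fits, statistic = c("adj_r2", "r2")) {
  statistic <- match.arg(statistic)
  ok <- Filter(function(f) inherits(f, "growth_fit") && f$converged &&
                 is.finite(f$r2), fits)
  if (length(ok) == 0L) stop_sg("no converged fits to select from")
  r2 <- vapply(ok, function(f) if (statistic == "adj_r2") f$adj_r2 else f$r2,
               numeric(1))
  npar <- vapply(ok, function(f) f$form$n_par, numeric(1))
  cat_ord <- match(vapply(ok, function(f) f$form$form_id, ""), form_ids())
  best <- which(r2 > max(r2) - 1e-12)
  best <- best[order(npar[best], cat_ord[best])][1]
  ok[[best]]
}

#' Extend a basic fit to its multivariate counterpart
#'
#' Builds the multivariate version of the selected basic form with the
#' given covariates appended in order (as predictors \eqn{x_2, x_3, \dots}),
#' plus the natural starting vector: the basic fit's parameters with every
#' covariate coefficient at zero.
#'
#' @param best a `growth_fit` of a basic form.
#' @param covariates 1--3 covariate names.
#' @return list with elements `form` (the multivariate [growth_form()]) and
#'   `init` (named start vector).
#' @export
extend_multivariate <- function(best, covariates) {
  stopifnot(inherits(best, "growth_fit"))
  if (best$form$n_covariates > 0) stop_sg("fit is already multivariate")
  if (length(covariates) < 1L || length(covariates) > 3L)
    stop_sg("need 1-3 covariates")
  form <- growth_form(best$form$form_id, covariates = covariates)
  init <- stats::setNames(c(unname(best$params), rep(0, length(covariates))),
                          form$par_names)
  list(form = form, init = init)
}

#' Fit the multivariate extension of a selected basic model
#'
#' Convenience wrapper: [extend_multivariate()] then [fit_nls()] on the
#' original response scale, starting from the basic fit's parameters.
#'
#' @param table inventory `data.frame` (modelling partition).
#' @param best the selected basic `growth_fit`.
#' @param covariates covariate names present in `table`.
#' @param relation relation id (see [fit_candidates()]).
#' @param species optional species label to subset.
#' @return a `growth_fit` of the multivariate form.
#' @export
fit_multivariate <- function(table, best, covariates, relation,
                             species = NULL) {
  sub <- if (is.null(species)) table
         else table[species_rows(table, species), , drop = FALSE]
  ext <- extend_multivariate(best, covariates)
  d <- relation_xy(sub, relation)
  Z <- as.matrix(sub[, covariates, drop = FALSE])
  fit_nls(ext$form, d$x, d$y, covariates = Z, init = ext$init)
}

#' Hold-out validation metrics
#'
#' Evaluates a fitted curve on a hold-out partition using the four standard
#' accuracy indicators, with residuals defined as predicted minus measured:
#' \deqn{ME = \frac{1}{n}\sum (\hat y_i - y_i), \quad
#'       MRE = \frac{1}{n}\sum \frac{\hat y_i - y_i}{y_i},}
#' \deqn{RMSE = \sqrt{\frac{\sum (\hat y_i - y_i)^2}{n - p}}, \quad
#'       R^2 = 1 - \frac{\sum (y_i - \hat y_i)^2}{\sum (y_i - \bar y)^2},}
#' where `p` is the number of independent variables of the model (1 for a
#' basic curve, 1 + number of covariates for a multivariate one) and
#' \eqn{\bar y} is the hold-out mean. Hold-out \eqn{R^2} may be negative;
#' RMSE is nonnegative by construction. If any \eqn{y_i = 0}, MRE is
#' reported as `NA` with a flag.
#'
#' @param fit a `growth_fit`.
#' @param holdout inventory `data.frame` (validation partition).
#' @param species optional species label to subset.
#' @return list of class `validation_metrics`: `me`, `mre`, `rmse`, `r2`,
#'   `n`, `p`, `mre_defined`.
#' @export
validate <- function(fit, holdout, species = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  sub <- if (is.null(species)) holdout
         else holdout[species_rows(holdout, species), , drop = FALSE]
  if (nrow(sub) == 0L) stop_sg("empty hold-out set")
  d <- relation_xy(sub, fit_relation(fit))
  Z <- if (fit$form$n_covariates > 0)
    as.matrix(sub[, fit$form$covariates, drop = FALSE]) else NULL
  pred <- eval_form_guarded(fit$form, fit$params, d$x, Z)
  validation_metrics(d$y, pred, p = 1L + fit$form$n_covariates)
}

#' @describeIn validate the metrics on raw observed/predicted vectors;
#'   `p` is the number of independent variables of the model that produced
#'   `predicted`.
#' @param observed,predicted numeric vectors (measured and model values).
#' @param p number of independent variables.
#' @export
validation_metrics <- function(observed, predicted, p = 1L) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  n <- length(observed)
  if (length(predicted) != n) stop_sg("observed and predicted lengths differ")
  if (n - p <= 0L) stop_sg("hold-out too small: n - p <= 0")
  err <- predicted - observed
  mre_defined <- !any(observed == 0)
  structure(list(
    me = mean(err),
    mre = if (mre_defined) mean(err / observed) else NA_real_,
    rmse = sqrt(sum(err^2) / (n - p)),
    r2 = 1 - sum(err^2) / sum((observed - mean(observed))^2),
    n = n, p = as.integer(p), mre_defined = mre_defined
  ), class = "validation_metrics")
}

# Relation bookkeeping: fits made through the workflow carry their relation;
# standalone fits fall back to an explicit attribute or error.
fit_relation <- function(fit) {
  rel <- attr(fit, "relation")
  if (is.null(rel))
    stop_sg("fit has no recorded relation; set attr(fit, 'relation')")
  rel
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("ME = %.3f  MRE = %.3f  RMSE = %.3f  R2 = %.3f  (n = %d, p = %d)\n",
              x$me, x$mre, x$rmse, x$r2, x$n, x$p))
  invisible(x)
}

#' Run the full per-species modelling workflow
#'
#' Orchestrates the complete analysis on one inventory table:
#' split into modelling/validation partitions; screen covariates against DBH
#' on the modelling partition and select the top `k`; run VIF diagnostics;
#' then, for every species and requested relation, fit all candidate basic
#' forms, select the best by modelling-set \eqn{R^2}, fit its multivariate
#' extension with the selected covariates, and validate both models on the
#' hold-out partition.
#'
#' @param table inventory `data.frame` with covariate columns.
#' @param relations subset of `c("dbh_height", "age_dbh")`.
#' @param fractions modelling/validation fractions (default 0.70/0.30).
#' @param seed seed for the random split.
#' @param stratify split within species (default `TRUE`, so each species
#'   keeps the global fractions).
#' @param k number of covariates to select (default 3).
#' @param rule screening ranking rule (default `"signed"`).
#' @param vif_threshold multicollinearity flag threshold (default 5).
#' @param forms candidate form ids.
#' @param species species labels to analyse (default: all in `table`).
#' @return list of class `growth_workflow` with elements `screening`
#'   (ranked correlations), `selected` (covariate names), `vif`, `split`
#'   (the two partitions) and `reports` — one entry per species x relation
#'   holding `candidate_fits`, `best`, `multivariate` and `validation`
#'   metrics for both models.
#' @export
run_workflow <- function(table, relations = relation_ids(),
                         fractions = c(0.7, 0.3), seed = 1L,
                         stratify = TRUE, k = 3L,
                         rule = c("signed", "absolute"), vif_threshold = 5,
                         forms = form_ids(), species = NULL) {
  rule <- match.arg(rule)
  relations <- match.arg(relations, relation_ids(), several.ok = TRUE)
  parts <- split_table(table, fractions, seed = seed,
                       stratify_by_species = stratify)
  model_set <- parts[[1]]; holdout <- parts[[2]]
  screening <- screen_covariates(model_set, response = "dbh", rule = rule)
  selected <- select_top(screening, k = k, rule = rule)
  vifs <- vif(model_set, selected, threshold = vif_threshold)
  species <- species %||% sort(unique(table$species))
  reports <- list()
  for (sp in species) for (rel in relations) {
    fits <- fit_candidates(model_set, species = sp, relation = rel,
                           forms = forms)
    best <- select_best(fits)
    attr(best, "relation") <- rel
    multi <- tryCatch({
      m <- fit_multivariate(model_set, best, selected, rel, species = sp)
      attr(m, "relation") <- rel
      m
    }, error = function(e)
      structure(list(form_id = best$form$form_id,
                     message = conditionMessage(e)),
                class = "growth_fit_error"))
    val_best <- tryCatch(validate(best, holdout, species = sp),
                         error = function(e) NULL)
    val_multi <- if (inherits(multi, "growth_fit"))
      tryCatch(validate(multi, holdout, species = sp),
               error = function(e) NULL)
    reports[[paste(sp, rel, sep = ".")]] <- structure(list(
      species = sp, relation = rel, candidate_fits = fits, best = best,
      multivariate = multi,
      validation = list(best = val_best, multivariate = val_multi)
    ), class = "species_report")
  }
  structure(list(screening = screening, selected = selected, vif = vifs,
                 split = parts, reports = reports, seed = seed),
            class = "growth_workflow")
}

#' @export
print.growth_workflow <- function(x, ...) {
  cat("<growth_workflow>\n")
  cat("  selected covariates:", paste(x$selected, collapse = ", "), "\n")
  for (rep in x$reports)
    cat(sprintf("  %-20s %-11s best: %-11s R2 = %.3f\n", rep$species,
                rep$relation, rep$best$form$form_id, rep$best$r2))
  invisible(x)
}

#' Build a report table from species reports
#'
#' Flattens workflow results into the familiar per-species tables:
#' `layout = "basic"` one row per species x candidate form with
#' \eqn{R^2}/F/df/p and coefficients; `"multivariate"` one row per species
#' with the fitted multivariate equation; `"validation"` one row per species
#' x model with ME, MRE and RMSE. Values are rounded to 3 decimals (full
#' precision lives in the fit objects / JSON serialization).
#'
#' @param reports a `growth_workflow`, or a list of its `species_report`
#'   entries.
#' @param layout `"basic"`, `"multivariate"` or `"validation"`.
#' @return a `data.frame`.
#' @export
build_report <- function(reports, layout = c("basic", "multivariate",
                                             "validation")) {
  layout <- match.arg(layout)
  if (inherits(reports, "growth_workflow")) reports <- reports$reports
  if (length(reports) == 0L) stop_sg("no reports")
  rows <- list()
  for (rep in reports) {
    if (layout == "basic") {
      for (f in rep$candidate_fits) {
        if (!inherits(f, "growth_fit")) next
        b <- unname(f$params)
        rows[[length(rows) + 1L]] <- data.frame(
          species = rep$species, relation = rep$relation,
          equation = f$form$form_id, r2 = round(f$r2, 3),
          f_value = round(f$f_value, 3), df1 = f$df1, df2 = f$df2,
          p_value = round(f$p_value, 3),
          b0 = round(if (f$form$form_id == "logistic") 0 else b[1], 3),
          b1 = round(if (f$form$form_id == "logistic") b[1] else b[2], 3),
          b2 = if (length(b) >= 3 || f$form$form_id == "logistic")
            round(if (f$form$form_id == "logistic") b[2] else b[3], 3)
            else NA_real_,
          b3 = if (length(b) >= 4 || f$form$form_id == "logistic")
            round(if (f$form$form_id == "logistic") b[3] else b[4], 3)
            else NA_real_)
      }
    } else if (layout == "multivariate") {
      m <- rep$multivariate
      if (!inherits(m, "growth_fit")) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = rep$species, relation = rep$relation,
        equation = equation_text(m$form, round(m$params, 4)),
        r2 = round(m$r2, 3), converged = m$converged)
    } else {
      for (which in c("best", "multivariate")) {
        v <- rep$validation[[which]]
        if (is.null(v)) next
        rows[[length(rows) + 1L]] <- data.frame(
          species = rep$species, relation = rep$relation, model = which,
          me = round(v$me, 3), mre = round(v$mre, 3),
          rmse = round(v$rmse, 3), r2 = round(v$r2, 3))
      }
    }
  }
  do.call(rbind, rows)
}
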