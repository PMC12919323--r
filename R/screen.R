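#' Screen environmental covariates by correlation with a response
#'
#' Computes the Pearson correlation of every covariate with the response
#' (DBH by default), one covariate at a time. Constant covariates are
#' reported with `r = NA` and placed last, excluded from ranking.
#'
#' @param table an inventory `data.frame`.
#' @param response field to correlate against (default `"dbh"`).
#' @param covariates covariate names; default all of
#'   [covariate_names()].
#' @param rule ranking rule used to order the result: `"signed"` sorts by
#'   `r` descending (so strong negative correlations rank last), the
#'   behaviour observed in classical covariate screening of this kind;
#'   `"absolute"` sorts by `|r|` descending.
#' @return data.frame with columns `name`, `r` and `catalogue` (the original
#'   covariate position, used for tie-breaking), ordered by the rule.
#' @export
screen_covariates <- function(table, response = "dbh", covariates = NULL,
                              rule = c("signed", "absolute")) {
  rule <- match.arg(rule)
  covariates <- covariates %||% covariate_names(table)
  if (nrow(table) < 3L) stop_sg("need at least 3 records to screen")
  y <- as.numeric(table[[response]])
  r <- vapply(covariates, function(nm) {
    v <- as.numeric(table[[nm]])
    if (stats::sd(v) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(v, y)
  }, numeric(1))
  if (all(is.na(r))) stop_sg("all covariates are constant; nothing to rank")
  out <- data.frame(name = covariates, r = unname(r),
                    catalogue = seq_along(covariates),
                    stringsAsFactors = FALSE)
  rank_screened(out, rule)
}

rank_screened <- function(screened, rule) {
  key <- if (rule == "absolute") -abs(screened$r) else -screened$r
  ord <- order(is.na(screened$r), key, screened$catalogue)
  out <- screened[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-k covariates from a screening result
#'
#' @param screened a data.frame as returned by [screen_covariates()] (needs
#'   `name`, `r` and optionally `catalogue` columns).
#' @param k number of covariates to keep (default 3).
#' @param rule `"signed"` ranks by `r` descending; `"absolute"` by `|r|`
#'   descending. Ties are broken by catalogue order.
#' @return character vector of `k` covariate names.
#' @examples
#' sc <- data.frame(name = c("dem", "p", "su"), r = c(0.52, 0.41, -0.46))
#' select_top(sc, k = 2, rule = "signed")
#' @export
select_top <- function(screened, k = 3L, rule = c("signed", "absolute")) {
  rule <- match.arg(rule)
  if (is.null(screened$catalogue)) screened$catalogue <- seq_len(nrow(screened))
  ranked <- rank_screened(screened, rule)
  ranked <- ranked[!is.na(ranked$r), , drop = FALSE]
  if (k > nrow(ranked))
    stop_sg(sprintf("k = %d exceeds the %d ranked covariates", k, nrow(ranked)))
  as.character(ranked$name[seq_len(k)])
}

#' Variance inflation factors
#'
#' For each covariate `j`, computes \eqn{VIF_j = 1 / (1 - R^2_j)} where
#' \eqn{R^2_j} comes from the OLS regression (with intercept) of covariate
#' `j` on the remaining covariates. Values above `threshold` (default 5)
#' flag multicollinearity.
#'
#' @param table an inventory `data.frame`.
#' @param covariates names of the covariates to diagnose (at least 2).
#' @param threshold flagging threshold.
#' @return named numeric vector of VIFs, with attributes `threshold` and
#'   `flagged` (names of covariates exceeding it).
#' @export
vif <- function(table, covariates, threshold = 5) {
  if (length(covariates) < 2L) stop_sg("VIF needs at least 2 covariates")
  if (nrow(table) < length(covariates) + 2L)
    stop_sg("too few records for VIF diagnostics")
  X <- sapply(covariates, function(nm) as.numeric(table[[nm]]))
  out <- vapply(seq_along(covariates), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    if (tot == 0) stop_sg(sprintf("covariate '%s' is constant", covariates[j]))
    r2j <- 1 - sum(res^2) / tot
    if (r2j > 1 - 1e-10)
      stop_sg(sprintf(
        "collinearity: '%s' is an exact linear combination of {%s}",
        covariates[j], paste(covariates[-j], collapse = ", ")))
    1 / (1 - r2j)
  }, numeric(1))
  names(out) <- covariates
  attr(out, "threshold") <- threshold
  attr(out, "flagged") <- covariates[out > threshold]
  out
}
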