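# Independent oracles and shared fixtures, kept deliberately naive so they
# stay independent of the implementation paths they check.

# Pearson correlation from the explicit covariance / sd formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# OLS through the normal equations, solved directly.
normal_eq_fit <- function(X, y) unname(drop(solve(t(X) %*% X, t(X) %*% y)))

# Hold-out metrics recomputed as one-liners.
metrics_oracle <- function(y, yhat, p) {
  list(me = sum(yhat - y) / length(y),
       mre = sum((yhat - y) / y) / length(y),
       rmse = sqrt(sum((yhat - y)^2) / (length(y) - p)),
       r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
}

# The published screening list (covariate symbol, correlation with DBH),
# in catalogue order.
screening_catalogue <- function() {
  data.frame(
    name = c("DEM", "P", "VPD", "TXx", "TXn", "TNn", "TNx", "DTR", "SU",
             "ID", "WSDI", "CSDI"),
    r = c(0.520, 0.410, -0.060, -0.420, 0.410, 0.350, -0.360, -0.167,
          -0.460, 0.400, 0.060, -0.340),
    stringsAsFactors = FALSE)
}

# The published per-species optimal-equation truths used as generating
# curves (DBH->height from the height table, age->DBH from the age table),
# with a plausible predictor range for each.
nonlinear_truths <- function() {
  list(
    list(form = "s_curve",  params = c(3.396, -12.923), range = c(6, 40)),
    list(form = "s_curve",  params = c(3.174, -8.341),  range = c(6, 40)),
    list(form = "s_curve",  params = c(2.181, -4.99),   range = c(6, 18)),
    list(form = "s_curve",  params = c(2.747, -8.481),  range = c(6, 26)),
    list(form = "growth",   params = c(2.053, 0.008),   range = c(16, 187)),
    list(form = "s_curve",  params = c(3.536, -17.461), range = c(9, 72)),
    list(form = "logistic", params = c(19.835, 0.205, 16.246),
         range = c(11, 25)),
    list(form = "s_curve",  params = c(3.259, -16.799), range = c(13, 50)))
}

# Random in-range parameter draws per form (base parameters only).
draw_base_params <- function(form_id) {
  switch(form_id,
    linear      = c(runif(1, -5, 10), runif(1, 0.1, 2)),
    logarithmic = c(runif(1, -15, 5), runif(1, 0.5, 8)),
    reciprocal  = c(runif(1, 5, 25), runif(1, -150, -5)),
    quadratic   = c(runif(1, -5, 5), runif(1, 0.2, 2),
                    runif(1, -0.03, -0.001)),
    cubic       = c(runif(1, -5, 5), runif(1, 0.5, 3),
                    runif(1, -0.08, -0.01), runif(1, 1e-4, 1e-3)),
    s_curve     = c(runif(1, 1.5, 3.5), runif(1, -20, -2)),
    growth      = c(runif(1, 0.5, 2.5), runif(1, 0.005, 0.05)),
    logistic    = c(runif(1, 5, 30), runif(1, 0.1, 0.7), runif(1, 10, 30)))
}

# Minimal valid inventory data.frame (no file round trip).
toy_inventory <- function(n = 60, seed = 1) {
  set.seed(seed)
  data.frame(species = "A", dbh = runif(n, 5, 40),
             height = runif(n, 2, 25), age = runif(n, 10, 120),
             dem = rnorm(n, 1800, 300), p = rnorm(n, 290, 40),
             txn = rnorm(n, -24, 1.5))
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
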