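# Small feedforward neural baseline: one hidden tanh layer, linear output,
# full-batch Levenberg-Marquardt with L2 weight decay and early stopping.

#' Neural-baseline configuration
#'
#' Defaults mirror the reference protocol: a single hidden layer of 10 tanh
#' units with linear output, Levenberg-Marquardt training with the damping
#' parameter initialized from the stated learning rate (0.01), L2 weight
#' decay 0.001, a 70/15/15 train/validation/test split, and early stopping
#' on validation loss.
#'
#' @param hidden_units hidden-layer width.
#' @param l2_weight_decay L2 penalty on connection weights (biases exempt).
#' @param learning_rate initial Levenberg-Marquardt damping.
#' @param split three fractions summing to 1.
#' @param early_stopping_patience epochs without validation improvement
#'   tolerated before stopping.
#' @param max_epochs epoch cap (one accepted LM step per epoch).
#' @param seed seed for weight initialization and the split.
#' @return list of class `nn_config`.
#' @export
nn_config <- function(hidden_units = 10L, l2_weight_decay = 0.001,
                      learning_rate = 0.01, split = c(0.70, 0.15, 0.15),
                      early_stopping_patience = 20L, max_epochs = 1000L,
                      seed = 1L) {
  stopifnot(hidden_units >= 1, l2_weight_decay >= 0, learning_rate > 0,
            length(split) == 3L, abs(sum(split) - 1) < 1e-9)
  structure(list(hidden_units = as.integer(hidden_units),
                 hidden_activation = "tanh", output_activation = "linear",
                 l2_weight_decay = l2_weight_decay,
                 learning_rate = learning_rate, split = split,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 max_epochs = as.integer(max_epochs), seed = seed),
            class = "nn_config")
}

nn_unpack <- function(theta, d, h) {
  list(W1 = matrix(theta[seq_len(h * d)], h, d),
       b1 = theta[h * d + seq_len(h)],
       w2 = theta[h * d + h + seq_len(h)],
       b2 = theta[h * d + 2L * h + 1L])
}

nn_forward <- function(theta, X, d, h) {
  p <- nn_unpack(theta, d, h)
  H <- tanh(sweep(X %*% t(p$W1), 2, p$b1, "+"))
  list(H = H, yhat = drop(H %*% p$w2) + p$b2)
}

# Jacobian of predictions wrt theta (n x P), analytic.
nn_jacobian <- function(theta, X, H, d, h) {
  p <- nn_unpack(theta, d, h)
  G <- sweep(1 - H^2, 2, p$w2, "*")            # n x h
  J <- matrix(0, nrow(X), h * d + 2L * h + 1L)
  for (k in seq_len(d))
    J[, (k - 1L) * h + seq_len(h)] <- G * X[, k]
  J[, h * d + seq_len(h)] <- G
  J[, h * d + h + seq_len(h)] <- H
  J[, h * d + 2L * h + 1L] <- 1
  J
}

#' Train the neural baseline
#'
#' Standardizes features and response with training-split statistics,
#' splits the data 70/15/15 (largest-remainder sizes, seeded shuffle), and
#' minimizes the L2-penalized squared loss by full-batch
#' Levenberg-Marquardt: each epoch solves
#' \eqn{(J^\top J + \mu I)\,\delta = J^\top r} (with the decay term folded
#' into the residual vector), accepting the step and shrinking \eqn{\mu}
#' when the penalized cost decreases, inflating \eqn{\mu} otherwise. The
#' weight snapshot with the best validation loss is retained (early
#' stopping). Training is bitwise-deterministic given the seed.
#'
#' Accuracy is reported per split both as the coefficient of determination
#' (`r2`) and as the Pearson correlation between predictions and
#' observations (`r`); test-set values are the headline metrics.
#'
#' @param features data.frame or matrix of predictors (n x d).
#' @param response numeric response vector.
#' @param config an [nn_config()].
#' @return object of class `growth_nn` with weights, standardization
#'   constants, per-split `r2` and `r`, split indices and training history.
#' @examples
#' x <- seq(0, 1, length.out = 60)
#' fit <- train_nn(data.frame(x = x), 3 * x,
#'                 nn_config(max_epochs = 50, seed = 2))
#' fit$r2$test
#' @export
train_nn <- function(features, response, config = nn_config()) {
  X0 <- as.matrix(features)
  storage.mode(X0) <- "double"
  y0 <- as.numeric(response)
  n <- nrow(X0); d <- ncol(X0); h <- config$hidden_units
  if (length(y0) != n) stop_sg("features and response lengths differ")
  if (n < 30L) stop_sg("need n >= 30 for a 70/15/15 split")
  sizes <- largest_remainder(n, config$split)
  if (any(sizes < 1L)) stop_sg("n too small: an empty split partition")
  idx <- with_seed(config$seed, sample.int(n))
  split_idx <- list(train = idx[seq_len(sizes[1])],
                    validation = idx[sizes[1] + seq_len(sizes[2])],
                    test = idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
  tr <- split_idx$train
  x_center <- colMeans(X0[tr, , drop = FALSE])
  x_scale <- apply(X0[tr, , drop = FALSE], 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(y0[tr]); y_scale <- stats::sd(y0[tr])
  if (y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X0, 2, x_center), 2, x_scale, "/")
  ys <- (y0 - y_center) / y_scale

  P <- h * d + 2L * h + 1L
  w_mask <- c(rep(TRUE, h * d), rep(FALSE, h), rep(TRUE, h), FALSE)
  theta <- with_seed(config$seed + 1L,
                     stats::rnorm(P, 0, 0.5) / sqrt(max(d, 1)))
  lam <- config$l2_weight_decay
  cost <- function(th, i) {
    fw <- nn_forward(th, Xs[i, , drop = FALSE], d, h)
    sum((ys[i] - fw$yhat)^2) + lam * sum(th[w_mask]^2)
  }
  val_loss <- function(th) {
    fw <- nn_forward(th, Xs[split_idx$validation, , drop = FALSE], d, h)
    mean((ys[split_idx$validation] - fw$yhat)^2)
  }

  mu <- config$learning_rate
  cur_cost <- cost(theta, tr)
  best_theta <- theta
  best_val <- val_loss(theta)
  stall <- 0L
  history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    fw <- nn_forward(theta, Xs[tr, , drop = FALSE], d, h)
    r <- ys[tr] - fw$yhat
    if (any(!is.finite(r)))
      stop_sg(sprintf("training diverged (non-finite loss at epoch %d)",
                      epoch))
    J <- nn_jacobian(theta, Xs[tr, , drop = FALSE], fw$H, d, h)
    g <- drop(crossprod(J, r)) - lam * theta * w_mask
    A0 <- crossprod(J) + diag(lam * w_mask, P)
    accepted <- FALSE
    for (try in 1:30) {
      delta <- tryCatch(solve(A0 + diag(mu, P), g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + delta
        cand_cost <- cost(cand, tr)
        if (is.finite(cand_cost) && cand_cost < cur_cost) {
          theta <- cand; cur_cost <- cand_cost
          mu <- max(mu / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
      if (mu > 1e12) break
    }
    vl <- val_loss(theta)
    history[epoch] <- vl
    if (vl < best_val - 1e-12) {
      best_val <- vl; best_theta <- theta; stall <- 0L
    } else stall <- stall + 1L
    if (!accepted || stall >= config$early_stopping_patience) break
  }

  obj <- structure(list(
    theta = best_theta, d = d, h = h,
    feature_names = colnames(X0) %||% paste0("x", seq_len(d)),
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    config = config, split_idx = split_idx,
    best_val_loss = best_val, final_val_loss = utils::tail(history, 1),
    epochs = length(history), history = history
  ), class = "growth_nn")
  metrics <- lapply(split_idx, function(i) {
    pred <- nn_predict(obj, X0[i, , drop = FALSE])
    obs <- y0[i]
    list(r2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
         r = suppressWarnings(stats::cor(pred, obs)))
  })
  obj$r2 <- lapply(metrics, `[[`, "r2")
  obj$r <- lapply(metrics, `[[`, "r")
  obj
}

#' Predict from a trained neural baseline
#'
#' Applies the stored standardization, the tanh layer and the linear output,
#' then maps back to the response scale. Deterministic.
#'
#' @param object a `growth_nn`.
#' @param features matrix/data.frame whose columns match the training
#'   features (by name when names are present, else by position).
#' @return numeric vector of predictions.
#' @export
nn_predict <- function(object, features) {
  stopifnot(inherits(object, "growth_nn"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (ncol(X) != object$d)
    stop_sg(sprintf("expected %d feature column(s), got %d", object$d,
                    ncol(X)))
  if (!is.null(colnames(X)) && !is.null(object$feature_names) &&
      !identical(colnames(X), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(X)))
      stop_sg("feature names do not match training features")
    X <- X[, object$feature_names, drop = FALSE]
  }
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  fw <- nn_forward(object$theta, Xs, object$d, object$h)
  fw$yhat * object$y_scale + object$y_center
}

#' @export
print.growth_nn <- function(x, ...) {
  cat(sprintf("<growth_nn> %d-%d-1 tanh network, %d epoch(s)\n",
              x$d, x$h, x$epochs))
  cat(sprintf("  R2: train %.3f  validation %.3f  test %.3f\n",
              x$r2$train, x$r2$validation, x$r2$test))
  invisible(x)
}
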