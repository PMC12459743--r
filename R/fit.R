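mlp_init <- function(H, D, M, range) {
  list(W1 = matrix(stats::runif(H * D, -range, range), H, D),
       b1 = stats::runif(H, -range, range),
       W2 = matrix(stats::runif(M * H, -range, range), M, H),
       b2 = stats::runif(M, -range, range))
}

mlp_forward <- function(w, X) {
  H <- tanh(X %*% t(w$W1) + matrix(w$b1, nrow(X), length(w$b1), byrow = TRUE))
  H %*% t(w$W2) + matrix(w$b2, nrow(X), length(w$b2), byrow = TRUE)
}

split_metrics <- function(w, X, Y) {
  Yhat <- mlp_forward(w, X)
  mse <- mean((Y - Yhat)^2)
  r2 <- mean(vapply(seq_len(ncol(Y)), function(j) {
    sst <- sum((Y[, j] - mean(Y[, j]))^2)
    1 - sum((Y[, j] - Yhat[, j])^2) / sst
  }, numeric(1)))
  c(mse = mse, r2 = r2)
}

#' Fit the nMVAR predictor with a one-hidden-layer network
#'
#' Trains a multilayer perceptron (one hidden tanh layer, linear output) to
#' predict the current sample of every channel from the stacked p past
#' samples of all channels. Training is incremental gradient descent with
#' momentum and an adaptive learning rate (increased after epochs that lower
#' the training error, decreased — with the step rejected — after epochs that
#' raise it beyond a tolerance), with early stopping on a validation split.
#' A k-fold permuted cross-validation protocol measures generalization: in
#' each fold the rows are randomly permuted and split 80/10/10 into
#' training, validation and test sets. The returned model is then refit on
#' all rows; that full-data fit has no validation set, so it stops when the
#' training error reaches a plateau (relative improvement below
#' `plateau_tol` over `plateau_window` epochs) or at `max_epochs`.
#'
#' @param regressors a `regressor_set` from [build_regressors()].
#' @param hidden number of hidden neurons H (default 10).
#' @param folds number of cross-validation folds (default 10). `folds = 1`
#'   trains once on a single 80/10/10 split and returns the early-stopped
#'   weights directly (used for surrogate refits).
#' @param momentum momentum coefficient (default 0.9).
#' @param learn_rate initial learning rate (default 0.005).
#' @param lr_up,lr_down multiplicative learning-rate adaptation factors
#'   (defaults 1.05 / 0.7).
#' @param max_perf_inc training-error increase ratio beyond which an epoch is
#'   rejected (default 1.04).
#' @param patience early-stopping patience in epochs (default 10).
#' @param max_epochs epoch cap (default 500).
#' @param init_range weights initialized uniformly on
#'   `(-init_range, init_range)` (default 0.5).
#' @param plateau_window,plateau_tol stopping rule for full-data fits (no
#'   validation set): stop when the training MSE improves by less than
#'   `plateau_tol` (relative) over `plateau_window` epochs (defaults 20 and
#'   1e-5).
#' @param full_data if TRUE, skip cross-validation entirely and train one
#'   model on all rows under the plateau rule — the identical configuration
#'   the final refit uses, applied to a surrogate dataset.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `ncreann_model` with the final weights,
#'   per-fold metrics (`metrics`), their across-fold summary
#'   (`mean_metrics`), the stopping epoch used for the final refit, training
#'   residuals, and the standardization moments inherited from the
#'   regressors.
#' @export
fit_ncreann <- function(regressors, hidden = 10, folds = 10,
                        momentum = 0.9, learn_rate = 0.005,
                        lr_up = 1.05, lr_down = 0.7, max_perf_inc = 1.04,
                        patience = 10, max_epochs = 500,
                        init_range = 0.5, plateau_window = 20,
                        plateau_tol = 1e-5, full_data = FALSE, seed = 1) {
  stopifnot(inherits(regressors, "regressor_set"), hidden >= 1, folds >= 1)
  X <- regressors$X; Y <- regressors$Y
  N <- nrow(X); D <- ncol(X); M <- ncol(Y)
  n_par <- hidden * (D + 1) + M * (hidden + 1)
  if (N < 10 * n_par)
    warning(sprintf("only %d rows for %d parameters (< 10x); fit may be unstable",
                    N, n_par))
  if (!is.null(seed)) set.seed(seed)

  train_once <- function(Xt, Yt, Xv, Yv, on_all_rows = FALSE) {
    init <- mlp_init(hidden, D, M, init_range)
    fe <- if (on_all_rows) max_epochs else 0L
    fit <- .mlp_train_cpp(Xt, Yt, Xv, Yv, init$W1, init$b1, init$W2, init$b2,
                          learn_rate, momentum, lr_up, lr_down, max_perf_inc,
                          patience, max_epochs, fe, plateau_window, plateau_tol)
    if (isTRUE(fit$diverged)) {
      fit <- .mlp_train_cpp(Xt, Yt, Xv, Yv, init$W1, init$b1, init$W2, init$b2,
                            learn_rate / 10, momentum, lr_up, lr_down,
                            max_perf_inc, patience, max_epochs, fe,
                            plateau_window, plateau_tol)
      if (isTRUE(fit$diverged)) stop("training diverged twice; aborting")
    }
    fit$b1 <- as.numeric(fit$b1)
    fit$b2 <- as.numeric(fit$b2)
    fit
  }

  if (isTRUE(full_data)) {
    fit <- train_once(X, Y, matrix(0, 0, D), matrix(0, 0, M),
                      on_all_rows = TRUE)
    w <- fit[c("W1", "b1", "W2", "b2")]
    mt <- split_metrics(w, X, Y)
    metrics <- data.frame(fold = 1L, stop_epoch = fit$epochs_run,
                          mse_train = mt["mse"], mse_val = NA_real_,
                          mse_test = NA_real_, r2_train = mt["r2"],
                          r2_test = NA_real_)
    return(structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                          hidden = hidden, M = M, p = regressors$p,
                          center = regressors$center, scale = regressors$scale,
                          channel_names = regressors$channel_names,
                          metrics = metrics,
                          mean_metrics = c(mse_train = unname(mt["mse"]),
                                           mse_train_sd = NA_real_,
                                           mse_test = NA_real_,
                                           mse_test_sd = NA_real_,
                                           r2_train = unname(mt["r2"]),
                                           r2_train_sd = NA_real_,
                                           r2_test = NA_real_,
                                           r2_test_sd = NA_real_),
                          stop_epoch = fit$epochs_run,
                          residuals = Y - mlp_forward(w, X),
                          config = list(folds = 0L, momentum = momentum,
                                        learn_rate = learn_rate, lr_up = lr_up,
                                        lr_down = lr_down,
                                        max_perf_inc = max_perf_inc,
                                        patience = patience,
                                        max_epochs = max_epochs,
                                        init_range = init_range,
                                        plateau_window = plateau_window,
                                        plateau_tol = plateau_tol,
                                        seed = seed)),
                     class = "ncreann_model"))
  }

  ntr <- floor(0.8 * N); nva <- floor(0.1 * N)
  if (ntr < 1 || nva < 1 || N - ntr - nva < 1)
    stop("too few rows for an 80/10/10 split")

  fold_fit <- vector("list", folds)
  metrics <- data.frame(fold = seq_len(folds), stop_epoch = NA_integer_,
                        mse_train = NA_real_, mse_val = NA_real_,
                        mse_test = NA_real_, r2_train = NA_real_,
                        r2_test = NA_real_)
  for (f in seq_len(folds)) {
    perm <- sample.int(N)
    itr <- perm[seq_len(ntr)]
    iva <- perm[ntr + seq_len(nva)]
    ite <- perm[(ntr + nva + 1):N]
    fit <- train_once(X[itr, , drop = FALSE], Y[itr, , drop = FALSE],
                      X[iva, , drop = FALSE], Y[iva, , drop = FALSE])
    w <- fit[c("W1", "b1", "W2", "b2")]
    mt <- split_metrics(w, X[itr, , drop = FALSE], Y[itr, , drop = FALSE])
    mv <- split_metrics(w, X[iva, , drop = FALSE], Y[iva, , drop = FALSE])
    me <- split_metrics(w, X[ite, , drop = FALSE], Y[ite, , drop = FALSE])
    metrics[f, -1] <- c(max(fit$best_epoch, 1L), mt["mse"], mv["mse"],
                        me["mse"], mt["r2"], me["r2"])
    fold_fit[[f]] <- w
  }

  fit <- train_once(X, Y, matrix(0, 0, D), matrix(0, 0, M),
                    on_all_rows = TRUE)
  w <- fit[c("W1", "b1", "W2", "b2")]
  stop_epoch <- fit$epochs_run

  resid <- Y - mlp_forward(w, X)
  mean_metrics <- c(
    mse_train = mean(metrics$mse_train), mse_train_sd = stats::sd(metrics$mse_train),
    mse_test = mean(metrics$mse_test), mse_test_sd = stats::sd(metrics$mse_test),
    r2_train = mean(metrics$r2_train), r2_train_sd = stats::sd(metrics$r2_train),
    r2_test = mean(metrics$r2_test), r2_test_sd = stats::sd(metrics$r2_test))

  structure(list(W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                 fold_weights = fold_fit,
                 hidden = hidden, M = M, p = regressors$p,
                 center = regressors$center, scale = regressors$scale,
                 channel_names = regressors$channel_names,
                 metrics = metrics, mean_metrics = mean_metrics,
                 stop_epoch = stop_epoch, residuals = resid,
                 config = list(folds = folds, momentum = momentum,
                               learn_rate = learn_rate, lr_up = lr_up,
                               lr_down = lr_down, max_perf_inc = max_perf_inc,
                               patience = patience, max_epochs = max_epochs,
                               init_range = init_range, seed = seed)),
            class = "ncreann_model")
}

#' @export
print.ncreann_model <- function(x, ...) {
  m <- x$mean_metrics
  cat(sprintf("<ncreann_model> M = %d, p = %d, H = %d (%d folds)\n",
              x$M, x$p, x$hidden, x$config$folds))
  cat(sprintf("  test MSE %.4f +- %.4f, test R2 %.4f +- %.4f (standardized scale)\n",
              m["mse_test"], m["mse_test_sd"], m["r2_test"], m["r2_test_sd"]))
  invisible(x)
}

#' @export
predict.ncreann_model <- function(object, newdata, ...) {
  if (inherits(newdata, "regressor_set")) newdata <- newdata$X
  mlp_forward(object, newdata)
}

#' Jacobian of the network output with respect to its input
#'
#' For the one-hidden-layer tanh network `f(x) = W2 tanh(W1 x + b1) + b2`,
#' the Jacobian at `x` is `W2 diag(1 - tanh^2(W1 x + b1)) W1` (M x M*p).
#'
#' @param model an `ncreann_model`.
#' @param x input vector of length M*p (the origin gives the linearization
#'   used for the linear-connectivity readout).
#' @return M x (M*p) Jacobian matrix.
#' @export
network_jacobian <- function(model, x = NULL) {
  if (is.null(x)) x <- numeric(ncol(model$W1))
  s <- 1 - tanh(as.numeric(model$W1 %*% x + model$b1))^2
  model$W2 %*% (s * model$W1)
}
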