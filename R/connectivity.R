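#' Decompose a trained nMVAR network into linear and nonlinear connectivity
#'
#' The fitted predictor f is split as `f = f_Lin + f_NonLin`. The linear part
#' is the best local-linear summary of f over the input distribution: its
#' coefficient matrix is the mean network Jacobian over a fixed random
#' subsample of training rows, `Jbar = mean_x J(x)` with
#' `J(x) = W2 diag(1 - tanh^2(W1 x + b1)) W1`. Linear connectivity averages
#' the absolute linearized coefficients over lags,
#' `LC[j, i] = mean_k |Jbar[j, (i, k)]|`; nonlinear connectivity measures how
#' much the local Jacobian varies around that summary,
#' `NC[j, i] = mean_x mean_k |J(x) - Jbar|[j, (i, k)]`. For a purely linear
#' system the Jacobian is constant, so LC matches the least-squares MVAR
#' coefficients and NC vanishes; for an even nonlinear coupling of a
#' symmetrically distributed parent the mean derivative is zero, so the edge
#' appears in NC only. (Linearizing at the origin instead would let part of
#' an even coupling leak into LC whenever the network's approximation of it
#' is asymmetric.)
#'
#' @param model an `ncreann_model`.
#' @param regressors the `regressor_set` the model was trained on.
#' @param n_eval number of evaluation rows for NC (default 2000; capped at
#'   the number of rows).
#' @param eval_seed seed for the evaluation subsample; `NULL` uses the
#'   current RNG stream.
#' @return An object of class `connectivity_result` with matrices `LC` and
#'   `NC` (rows = target j, columns = source i, entry = i -> j), both
#'   non-negative, plus bookkeeping fields.
#' @export
decompose_connectivity <- function(model, regressors, n_eval = 2000,
                                   eval_seed = 1) {
  stopifnot(inherits(model, "ncreann_model"),
            inherits(regressors, "regressor_set"))
  if (model$M != regressors$M || model$p != regressors$p)
    stop("model and regressors disagree on M or p")
  M <- model$M; p <- model$p
  lag_mean <- function(J) {
    out <- matrix(0, M, M)
    for (k in seq_len(p))
      out <- out + J[, (k - 1) * M + seq_len(M), drop = FALSE]
    out / p
  }

  N <- nrow(regressors$X)
  if (!is.null(eval_seed)) set.seed(eval_seed)
  idx <- if (N > n_eval) sort(sample.int(N, n_eval)) else seq_len(N)
  Xe <- regressors$X[idx, , drop = FALSE]

  A <- tanh(Xe %*% t(model$W1) +
              matrix(model$b1, length(idx), model$hidden, byrow = TRUE))
  S <- 1 - A^2                       # rows x H: tanh slopes per sample
  sbar <- colMeans(S)
  Jbar <- model$W2 %*% (sbar * model$W1)   # J is linear in the slope vector
  LC <- lag_mean(abs(Jbar))
  acc <- matrix(0, M, M * p)
  for (r in seq_along(idx))
    acc <- acc + abs(model$W2 %*% ((S[r, ] - sbar) * model$W1))
  NC <- lag_mean(acc / length(idx))

  nm <- model$channel_names
  dimnames(LC) <- dimnames(NC) <- list(target = nm, source = nm)
  structure(list(LC = LC, NC = NC, M = M, p = p,
                 n_eval = length(idx),
                 channel_names = nm),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> M = %d nodes (entry [j, i] = i -> j)\n", x$M))
  cat("LC:\n"); print(round(x$LC, 4))
  cat("NC:\n"); print(round(x$NC, 4))
  if (!is.null(x$p_LC)) {
    cat("significant LC edges (alpha =", x$alpha, "):",
        sum(x$significant_LC, na.rm = TRUE), "\n")
    cat("significant NC edges:", sum(x$significant_NC, na.rm = TRUE), "\n")
  }
  invisible(x)
}

#' Time-shifted surrogate series
#'
#' Builds null datasets by circularly shifting every channel of the
#' concatenated series by its own random offset. Each channel's marginal
#' distribution and (circular) autocorrelation are preserved exactly, while
#' cross-channel temporal alignment — and with it any directed coupling — is
#' destroyed. Offsets are drawn uniformly on
#' `[min_shift_fraction * L, (1 - min_shift_fraction) * L]`, with the
#' additional requirement that every *pair* of channels differs by at least
#' `min_shift_fraction * L` (circularly): two channels shifted by nearly the
#' same offset would keep their mutual alignment, leaving residual coupling
#' in the null. Offset sets violating the pairwise rule are redrawn.
#'
#' @param series L x M matrix (concatenated node time courses).
#' @param n_surrogates number of surrogate datasets (default 100).
#' @param min_shift_fraction minimum shift as a fraction of L (default 0.1).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return list with `series` (list of L x M shifted matrices) and `shifts`
#'   (n_surrogates x M integer matrix).
#' @export
time_shift_surrogates <- function(series, n_surrogates = 100,
                                  min_shift_fraction = 0.1, seed = 1) {
  stopifnot(is.matrix(series), n_surrogates >= 1,
            min_shift_fraction > 0, min_shift_fraction < 0.5)
  L <- nrow(series); M <- ncol(series)
  lo <- ceiling(min_shift_fraction * L)
  hi <- floor((1 - min_shift_fraction) * L)
  if (lo > hi) stop("series too short for min_shift_fraction = ", min_shift_fraction)
  if (!is.null(seed)) set.seed(seed)
  if (M > 1 && (hi - lo + 1) < 2 * M * lo)
    stop("series too short to separate ", M,
         " channels by min_shift_fraction = ", min_shift_fraction)
  draw_one <- function() {
    for (it in 1:1000) {
      sh <- sample(lo:hi, M, replace = TRUE)
      d <- abs(outer(sh, sh, "-"))
      d <- pmin(d, L - d)                 # circular pairwise offsets
      if (M == 1 || min(d[upper.tri(d)]) >= lo) return(sh)
    }
    stop("could not draw pairwise-separated shifts")
  }
  shifts <- t(vapply(seq_len(n_surrogates), function(s) draw_one(),
                     integer(M)))
  out <- lapply(seq_len(n_surrogates), function(s) {
    sh <- series
    for (ch in seq_len(M)) {
      k <- shifts[s, ch]
      sh[, ch] <- series[c((k + 1):L, 1:k), ch]
    }
    sh
  })
  list(series = out, shifts = shifts)
}

#' Surrogate-based edge significance
#'
#' One-sided empirical p-values with the add-one correction,
#' `p = (1 + #\{surrogate >= observed\}) / (1 + n_surrogates)`, per edge and
#' per connectivity kind. Self-connections are excluded from the masks.
#'
#' @param observed a `connectivity_result`.
#' @param surrogate_LC,surrogate_NC arrays n_surrogates x M x M of surrogate
#'   connectivity values.
#' @param alpha significance level (default 0.05).
#' @return the `connectivity_result` augmented with `p_LC`, `p_NC`,
#'   `significant_LC`, `significant_NC` (diagonals NA), `alpha`,
#'   `n_surrogates`.
#' @export
surrogate_significance <- function(observed, surrogate_LC, surrogate_NC,
                                   alpha = 0.05) {
  stopifnot(inherits(observed, "connectivity_result"))
  if (is.null(surrogate_LC) || is.null(surrogate_NC))
    stop("surrogate results are required")
  ns <- dim(surrogate_LC)[1]
  if (ns < 20 && alpha <= 0.05)
    warning("fewer than 20 surrogates for alpha = ", alpha,
            "; p-values are coarse")
  emp_p <- function(obs, surr) {
    M <- nrow(obs)
    p <- matrix(NA_real_, M, M, dimnames = dimnames(obs))
    for (j in seq_len(M)) for (i in seq_len(M))
      p[j, i] <- (1 + sum(surr[, j, i] >= obs[j, i])) / (1 + ns)
    p
  }
  observed$p_LC <- emp_p(observed$LC, surrogate_LC)
  observed$p_NC <- emp_p(observed$NC, surrogate_NC)
  mk_mask <- function(p) {
    m <- p < alpha
    diag(m) <- NA
    m
  }
  observed$significant_LC <- mk_mask(observed$p_LC)
  observed$significant_NC <- mk_mask(observed$p_NC)
  observed$alpha <- alpha
  observed$n_surrogates <- ns
  observed$surrogate_LC <- surrogate_LC
  observed$surrogate_NC <- surrogate_NC
  observed
}

#' Estimate directed connectivity with surrogate significance testing
#'
#' The full estimator: builds lagged regressors from the node time courses,
#' trains the network predictor with the cross-validated protocol, decomposes
#' it into linear (LC) and nonlinear (NC) directed connectivity, then repeats
#' the identical fit-and-decompose procedure on time-shifted surrogate
#' datasets and derives empirical edge p-values. Each surrogate dataset is
#' refit with the identical network configuration as the observed data: the
#' same architecture, training algorithm and full-data plateau-stopping rule
#' that produce the observed final model, so observed and surrogate
#' connectivity values are exchangeable when no coupling is present.
#'
#' @param x node time courses (any form accepted by [build_regressors()]).
#' @param order model order p (default 10).
#' @param window_ms,fs_hz,t0_ms forwarded to [build_regressors()].
#' @param hidden hidden-layer size (default 10).
#' @param folds cross-validation folds for the observed fit (default 10).
#' @param n_surrogates number of time-shifted surrogates (default 100).
#' @param min_shift_fraction minimum surrogate shift fraction (default 0.1).
#' @param alpha significance level (default 0.05).
#' @param n_eval evaluation rows for the NC readout (default 2000).
#' @param seed master seed for the whole estimation (default 1).
#' @param ... further training options passed to [fit_ncreann()].
#' @return a `connectivity_result` with significance fields and the fitted
#'   `model` attached.
#' @export
estimate_connectivity <- function(x, order = 10, window_ms = NULL,
                                  fs_hz = NULL, t0_ms = NULL,
                                  hidden = 10, folds = 10,
                                  n_surrogates = 100,
                                  min_shift_fraction = 0.1,
                                  alpha = 0.05, n_eval = 2000, seed = 1, ...) {
  set.seed(seed)
  reg <- build_regressors(x, order, window_ms, fs_hz, t0_ms)
  model <- fit_ncreann(reg, hidden = hidden, folds = folds, seed = NULL, ...)
  obs <- decompose_connectivity(model, reg, n_eval = n_eval, eval_seed = NULL)

  M <- reg$M
  surr_LC <- array(NA_real_, dim = c(n_surrogates, M, M))
  surr_NC <- array(NA_real_, dim = c(n_surrogates, M, M))
  if (n_surrogates > 0) {
    surr <- time_shift_surrogates(reg$series, n_surrogates,
                                  min_shift_fraction, seed = NULL)
    for (s in seq_len(n_surrogates)) {
      reg_s <- build_regressors(list(series = surr$series[[s]],
                                     trial_id = reg$trial_id),
                                order = order)
      model_s <- fit_ncreann(reg_s, hidden = hidden, full_data = TRUE,
                             seed = NULL, ...)
      conn_s <- decompose_connectivity(model_s, reg_s, n_eval = n_eval,
                                       eval_seed = NULL)
      surr_LC[s, , ] <- conn_s$LC
      surr_NC[s, , ] <- conn_s$NC
    }
    obs <- surrogate_significance(obs, surr_LC, surr_NC, alpha)
  }
  obs$model <- model
  obs$seed <- seed
  obs
}

#' Long-format export of a connectivity result
#'
#' @param conn a `connectivity_result`.
#' @param band,condition optional annotation columns.
#' @return data frame with one row per ordered node pair (self-connections
#'   excluded): source, target, band, condition, LC, NC, p_LC, p_NC.
#' @export
connectivity_table <- function(conn, band = NA_character_,
                               condition = NA_character_) {
  stopifnot(inherits(conn, "connectivity_result"))
  M <- conn$M
  nm <- conn$channel_names
  rows <- list()
  for (j in seq_len(M)) for (i in seq_len(M)) {
    if (i == j) next
    rows[[length(rows) + 1]] <- data.frame(
      source = nm[i], target = nm[j], band = band, condition = condition,
      LC = conn$LC[j, i], NC = conn$NC[j, i],
      p_LC = if (!is.null(conn$p_LC)) conn$p_LC[j, i] else NA_real_,
      p_NC = if (!is.null(conn$p_NC)) conn$p_NC[j, i] else NA_real_)
  }
  do.call(rbind, rows)
}
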