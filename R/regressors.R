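#' @useDynLib ncreann, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Normalize node-timecourse input to a concatenated series + trial ids.
# Accepted forms: L x M matrix; list(series, trial_id); trials x M x samples
# array (optionally cropped to a window).
as_node_series <- function(x, window_ms = NULL, fs_hz = NULL, t0_ms = NULL) {
  if (is.list(x) && !is.null(x$series)) {
    stopifnot(length(x$trial_id) == nrow(x$series))
    return(list(series = as.matrix(x$series), trial_id = as.integer(x$trial_id)))
  }
  if (is.matrix(x))
    return(list(series = x, trial_id = rep(1L, nrow(x))))
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    idx <- seq_len(d[3])
    if (!is.null(window_ms)) {
      stopifnot(!is.null(fs_hz), !is.null(t0_ms))
      t_ms <- t0_ms + (idx - 1) * 1000 / fs_hz
      idx <- which(t_ms >= window_ms[1] & t_ms < window_ms[2])
      if (!length(idx)) stop("analysis window lies outside the epoch support")
    }
    series <- do.call(rbind, lapply(seq_len(d[1]), function(tr)
      t(matrix(x[tr, , idx], nrow = d[2]))))
    trial_id <- rep(seq_len(d[1]), each = length(idx))
    return(list(series = series, trial_id = trial_id))
  }
  stop("unsupported node-timecourse input")
}

#' Build the lagged regressor set for nMVAR fitting
#'
#' Stacks, for every usable sample n, the vector of p past values of all M
#' channels (lag-major column order: x1(n-1), ..., xM(n-1), x1(n-2), ...,
#' xM(n-p)) against the current values. Rows never span a trial boundary: the
#' first p samples of each trial serve only as history. Channels are
#' standardized (mean 0, SD 1) using moments computed over all included
#' samples, so fit metrics live on a common scale.
#'
#' @param x node time courses: an L x M matrix, a `list(series, trial_id)`
#'   with trials concatenated, a trials x M x samples array, or an
#'   `eeg_epochs`.
#' @param order model order p (past samples per channel).
#' @param window_ms analysis window relative to stimulus onset, applied to
#'   epoched input (default `c(0, 1000)` when epochs are given).
#' @param fs_hz,t0_ms timing metadata for plain-array input.
#' @param standardize standardize channels (default TRUE).
#' @return An object of class `regressor_set`: `X` (rows x M*p), `Y`
#'   (rows x M), `M`, `p`, `n`, `center`, `scale`, `series` (the
#'   standardized concatenated series), `trial_id`.
#' @export
build_regressors <- function(x, order, window_ms = NULL, fs_hz = NULL,
                             t0_ms = NULL, standardize = TRUE) {
  stopifnot(order >= 1)
  if (inherits(x, "eeg_epochs")) {
    if (is.null(window_ms)) window_ms <- c(0, 1000)
    ns <- as_node_series(x$data, window_ms, x$fs_hz, x$t0_ms)
  } else {
    ns <- as_node_series(x, window_ms, fs_hz, t0_ms)
  }
  series <- ns$series
  M <- ncol(series)
  trials <- unique(ns$trial_id)
  per_trial <- table(ns$trial_id)
  if (any(per_trial <= order))
    stop("every trial window must contain more than p samples")
  if (standardize) {
    center <- colMeans(series)
    scl <- apply(series, 2, stats::sd)
    if (any(scl == 0)) stop("constant channel cannot be standardized")
    series <- scale(series, center = center, scale = scl)
    attributes(series)[c("scaled:center", "scaled:scale")] <- NULL
  } else {
    center <- rep(0, M); scl <- rep(1, M)
  }
  n_rows <- sum(pmax(0, as.integer(per_trial) - order))
  X <- matrix(0, n_rows, M * order)
  Y <- matrix(0, n_rows, M)
  pos <- 0L
  for (tr in trials) {
    rows <- which(ns$trial_id == tr)
    s <- series[rows, , drop = FALSE]
    nt <- nrow(s)
    tt <- (order + 1):nt
    out_rows <- pos + seq_along(tt)
    Y[out_rows, ] <- s[tt, , drop = FALSE]
    for (k in seq_len(order))
      X[out_rows, (k - 1) * M + seq_len(M)] <- s[tt - k, , drop = FALSE]
    pos <- pos + length(tt)
  }
  ch <- colnames(series)
  if (is.null(ch)) ch <- paste0("x", seq_len(M))
  colnames(Y) <- ch
  colnames(X) <- as.vector(vapply(seq_len(order), function(k)
    paste0(ch, "_lag", k), character(M)))
  structure(list(X = X, Y = Y, M = M, p = as.integer(order), n = n_rows,
                 center = center, scale = scl,
                 series = series, trial_id = ns$trial_id,
                 channel_names = ch),
            class = "regressor_set")
}

#' @export
print.regressor_set <- function(x, ...) {
  cat(sprintf("<regressor_set> %d rows, M = %d channels, p = %d (%d inputs)\n",
              x$n, x$M, x$p, x$M * x$p))
  invisible(x)
}

#' Select the MVAR model order by information criteria
#'
#' Fits linear MVAR models of order 1..p_max by least squares on a common
#' sample range and scores them with the Akaike and Schwartz (Bayesian)
#' information criteria based on the log-determinant of the residual
#' covariance. Returns the AIC minimizer and the full criterion table.
#'
#' @param x node time courses (any form accepted by [build_regressors()]).
#' @param p_max maximum order to consider.
#' @param ... passed on to [build_regressors()] (window, timing).
#' @return list of class `order_selection`: `order` (AIC choice),
#'   `order_bic`, `table` (data frame p / aic / bic).
#' @export
select_model_order <- function(x, p_max, ...) {
  if (p_max < 1) stop("p_max must be at least 1")
  reg <- build_regressors(x, order = p_max, ...)
  N <- reg$n; M <- reg$M
  if (N <= p_max * M + 1) stop("series too short for p_max = ", p_max)
  rows <- list()
  for (p in seq_len(p_max)) {
    Xp <- cbind(1, reg$X[, seq_len(M * p), drop = FALSE])
    q <- qr(Xp)
    if (q$rank < ncol(Xp)) {
      warning("rank-deficient regression at p = ", p, "; skipped")
      next
    }
    res <- qr.resid(q, reg$Y)
    Sigma <- crossprod(res) / N
    ld <- determinant(Sigma, logarithm = TRUE)$modulus
    k <- p * M^2
    rows[[length(rows) + 1]] <- data.frame(
      p = p, aic = as.numeric(N * ld + 2 * k),
      bic = as.numeric(N * ld + log(N) * k))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("no order could be fitted")
  structure(list(order = tab$p[which.min(tab$aic)],
                 order_bic = tab$p[which.min(tab$bic)],
                 table = tab),
            class = "order_selection")
}

#' @export
print.order_selection <- function(x, ...) {
  cat(sprintf("<order_selection> AIC order = %d, BIC order = %d\n",
              x$order, x$order_bic))
  print(x$table, row.names = FALSE)
  invisible(x)
}
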