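#' AR(2) coefficients for a band-limited oscillatory carrier
#'
#' Places a complex-conjugate pole pair at the requested peak frequency so the
#' resulting AR(2) process has a narrowband spectral peak there. The closer
#' the pole radius is to 1, the sharper the peak.
#'
#' @param peak_freq_hz desired spectral peak, in Hz (0 < f < fs/2).
#' @param fs_hz sampling rate in Hz.
#' @param pole_radius pole modulus r, 0 <= r < 1.
#' @return numeric vector `c(a1, a2)` with
#'   `a1 = 2 r cos(2 pi f / fs)`, `a2 = -r^2`.
#' @examples
#' ar2_coefficients(10, 256, 0.95)  # c(1.8431, -0.9025)
#' @export
ar2_coefficients <- function(peak_freq_hz, fs_hz, pole_radius) {
  stopifnot(fs_hz > 0)
  if (peak_freq_hz <= 0 || peak_freq_hz >= fs_hz / 2)
    stop("peak_freq_hz must lie strictly inside (0, fs/2)")
  if (pole_radius < 0 || pole_radius >= 1)
    stop("pole_radius must be in [0, 1) for a stable AR(2)")
  c(a1 = 2 * pole_radius * cos(2 * pi * peak_freq_hz / fs_hz),
    a2 = -pole_radius^2)
}

#' Define a ground-truth nonlinear MVAR system
#'
#' Specifies the generating model used by [simulate_nmvar()]: each channel is
#' an autoregression of order `p` on all channels, plus optional nonlinear
#' coupling terms that act on the *standardized* value of a parent channel.
#' Standardizing parents keeps the signal-to-innovation ratio of each coupled
#' channel controlled by the coupling gains alone.
#'
#' @param linear_coeffs numeric array M x M x p; `linear_coeffs[j, i, k]` is
#'   the coefficient of channel `i` at lag `k` in the equation of channel `j`.
#' @param nonlinear_terms list of terms, each a list with fields `target`,
#'   `source`, `lag`, `fun` (one of `"square_centered"`, meaning z^2 - 1, or
#'   `"tanh"`), and `gain`.
#' @param innovation_sd per-channel innovation standard deviations.
#' @param burn_in samples discarded at the start (default 1000).
#' @param standardize_parents if TRUE (default) cross-channel terms (linear
#'   and nonlinear) act on parents standardized by their own post-burn-in
#'   moments, and the coupling graph must be acyclic; if FALSE all channels
#'   are simulated jointly on the raw scale.
#' @return An object of class `nmvar_system`.
#' @export
nmvar_system <- function(linear_coeffs, nonlinear_terms = list(),
                         innovation_sd, burn_in = 1000,
                         standardize_parents = TRUE) {
  stopifnot(is.array(linear_coeffs), length(dim(linear_coeffs)) == 3)
  M <- dim(linear_coeffs)[1]
  p <- dim(linear_coeffs)[3]
  stopifnot(dim(linear_coeffs)[2] == M, length(innovation_sd) == M,
            all(innovation_sd >= 0), burn_in >= 0)
  for (term in nonlinear_terms) {
    stopifnot(all(c("target", "source", "lag", "fun", "gain") %in% names(term)))
    stopifnot(term$target %in% seq_len(M), term$source %in% seq_len(M),
              term$lag >= 1,
              term$fun %in% c("square_centered", "tanh"))
  }
  p_true <- max(p, vapply(nonlinear_terms, function(t) t$lag, numeric(1), USE.NAMES = FALSE), 1)
  sys <- structure(list(M = M, p = as.integer(p_true),
                        linear_coeffs = linear_coeffs,
                        nonlinear_terms = nonlinear_terms,
                        innovation_sd = innovation_sd,
                        burn_in = as.integer(burn_in),
                        standardize_parents = isTRUE(standardize_parents)),
                   class = "nmvar_system")
  sr <- nmvar_spectral_radius(sys)
  if (sr >= 1)
    stop(sprintf("linear subsystem is unstable (companion spectral radius %.3f >= 1)", sr))
  sys
}

#' Spectral radius of the companion matrix of the linear subsystem
#' @param system an `nmvar_system`.
#' @return largest eigenvalue modulus; < 1 means the linear part is stable.
#' @export
nmvar_spectral_radius <- function(system) {
  A <- system$linear_coeffs
  M <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, M * p, M * p)
  for (k in seq_len(p)) comp[1:M, (k - 1) * M + 1:M] <- A[, , k]
  if (p > 1) comp[(M + 1):(M * p), 1:(M * (p - 1))] <- diag(M * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' The three-channel simulation benchmark B1
#'
#' A minimal system with one exogenous narrowband driver and two driven
#' channels: channel 1 is an AR(2) oscillator (poles at radius 0.95, peak at
#' 10 Hz for fs = 256 Hz); channel 2 receives a purely linear lag-1 influence
#' from the standardized driver (gain 0.80); channel 3 receives a purely
#' nonlinear, even-function influence (0.60 * (z^2 - 1)) that a first-order
#' (linear) analysis cannot see. True directed edges: linear 1 -> 2,
#' nonlinear 1 -> 3.
#'
#' @return An `nmvar_system` describing the benchmark.
#' @export
benchmark_b1 <- function() {
  A <- array(0, dim = c(3, 3, 2))
  ar <- ar2_coefficients(10, 256, 0.95)
  A[1, 1, 1] <- ar[1]; A[1, 1, 2] <- ar[2]
  A[2, 2, 1] <- 0.55
  A[3, 3, 1] <- 0.55
  A[2, 1, 1] <- 0.80
  nl <- list(list(target = 3, source = 1, lag = 1,
                  fun = "square_centered", gain = 0.60))
  nmvar_system(A, nl, innovation_sd = c(1, 0.12, 0.12), burn_in = 1000)
}

nl_fun <- function(tag, z) {
  switch(tag,
         square_centered = z^2 - 1,
         tanh = tanh(z),
         stop("unknown nonlinear function tag: ", tag))
}

# topological order of the cross-channel coupling graph; error if cyclic
coupling_order <- function(system) {
  M <- system$M
  parents <- vector("list", M)
  A <- system$linear_coeffs
  for (j in seq_len(M)) {
    pj <- which(apply(abs(A[j, , , drop = FALSE]), 2, sum) > 0)
    parents[[j]] <- setdiff(pj, j)
  }
  for (term in system$nonlinear_terms)
    if (term$source != term$target)
      parents[[term$target]] <- union(parents[[term$target]], term$source)
  order <- integer(0); remaining <- seq_len(M)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(j)
      all(parents[[j]] %in% order), logical(1))]
    if (!length(ready))
      stop("coupling graph is cyclic; use standardize_parents = FALSE")
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Simulate a nonlinear MVAR system
#'
#' Generates `n_samples` post-burn-in samples from a ground-truth system.
#' With standardized parents (the default), channels are generated in
#' topological order of the coupling graph: each parent is simulated fully,
#' standardized by its own post-burn-in mean and SD, and those z-values feed
#' the linear and nonlinear cross-channel terms of its children.
#'
#' @param system an `nmvar_system`.
#' @param n_samples number of post-burn-in samples L.
#' @param seed integer seed.
#' @return list with `series` (L x M matrix), `linear_edges` and
#'   `nonlinear_edges` (M x M logical matrices, entry `[j, i]` = edge i -> j,
#'   self-edges excluded).
#' @export
simulate_nmvar <- function(system, n_samples, seed = 1) {
  stopifnot(inherits(system, "nmvar_system"), n_samples > 10 * system$p)
  M <- system$M; p <- system$p
  n <- system$burn_in + n_samples
  A <- system$linear_coeffs
  pA <- dim(A)[3]
  set.seed(seed)
  innov <- sapply(seq_len(M), function(j) stats::rnorm(n, sd = system$innovation_sd[j]))
  post <- (system$burn_in + 1):n

  x <- matrix(0, n, M)
  if (system$standardize_parents) {
    z <- matrix(0, n, M)
    for (j in coupling_order(system)) {
      nl_j <- Filter(function(t) t$target == j, system$nonlinear_terms)
      for (t in (p + 1):n) {
        v <- innov[t, j]
        for (k in seq_len(pA)) {
          v <- v + A[j, j, k] * x[t - k, j]
          for (i in seq_len(M)[-j]) if (A[j, i, k] != 0)
            v <- v + A[j, i, k] * z[t - k, i]
        }
        for (term in nl_j) {
          parent <- if (term$source == j) x[t - term$lag, j] else z[t - term$lag, term$source]
          v <- v + term$gain * nl_fun(term$fun, parent)
        }
        x[t, j] <- v
      }
      z[, j] <- (x[, j] - mean(x[post, j])) / stats::sd(x[post, j])
    }
  } else {
    for (t in (p + 1):n) {
      v <- innov[t, ]
      for (k in seq_len(pA)) v <- v + A[, , k] %*% x[t - k, ]
      for (term in system$nonlinear_terms)
        v[term$target] <- v[term$target] +
          term$gain * nl_fun(term$fun, x[t - term$lag, term$source])
      x[t, ] <- v
    }
  }

  lin <- matrix(FALSE, M, M); nl <- matrix(FALSE, M, M)
  for (k in seq_len(pA)) lin <- lin | (A[, , k] != 0)
  for (term in system$nonlinear_terms) nl[term$target, term$source] <- TRUE
  diag(lin) <- FALSE; diag(nl) <- FALSE
  dn <- list(paste0("to_", seq_len(M)), paste0("from_", seq_len(M)))
  dimnames(lin) <- dn; dimnames(nl) <- dn

  series <- x[post, , drop = FALSE]
  colnames(series) <- paste0("x", seq_len(M))
  list(series = series, linear_edges = lin, nonlinear_edges = nl)
}
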