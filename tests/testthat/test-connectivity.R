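test_that("time-shifted surrogates preserve marginals and autocorrelation", {
  sim <- b1_sim(2000, seed = 1)
  s <- scale(sim$series)
  surr <- time_shift_surrogates(s, n_surrogates = 5, seed = 2)
  for (k in 1:5) {
    sh <- surr$series[[k]]
    for (ch in 1:3) {
      expect_equal(mean(sh[, ch]), mean(s[, ch]), tolerance = 1e-12)
      expect_equal(var(sh[, ch]), var(s[, ch]), tolerance = 1e-12)
      expect_setequal(sh[, ch], s[, ch])
      # circular autocorrelation is shift-invariant
      circ_acf <- function(v, lag) cor(v, v[c((lag + 1):length(v), 1:lag)])
      for (lag in c(1, 5)) {
        expect_equal(circ_acf(sh[, ch], lag), circ_acf(s[, ch], lag),
                     tolerance = 1e-10)
      }
    }
  }
  expect_equal(dim(surr$shifts), c(5, 3))
})

test_that("surrogate shifts are pairwise separated and break coupling", {
  sim <- b1_sim(4000, seed = 2)
  s <- sim$series
  L <- nrow(s)
  surr <- time_shift_surrogates(s, n_surrogates = 20, seed = 3)
  lo <- ceiling(0.1 * L)
  # sampling bound for the cross-correlation of two independent but
  # autocorrelated (narrowband) series
  bound <- 4 * bartlett_sd(s[, 1], s[, 2])
  expect_gt(abs(cor(s[-1, 2], s[-L, 1])), bound)   # coupled before shifting
  for (k in 1:20) {
    sh <- surr$shifts[k, ]
    d <- abs(outer(sh, sh, "-")); d <- pmin(d, L - d)
    expect_gte(min(d[upper.tri(d)]), lo)
    # coupled channels decorrelate after shifting
    x <- surr$series[[k]]
    expect_lt(abs(cor(x[-1, 2], x[-L, 1])), bound)
  }
  expect_error(time_shift_surrogates(s[1:20, ], 5, 0.4), "too short")
})

test_that("empirical p-values follow the add-one rank rule", {
  obs <- structure(list(LC = matrix(2, 2, 2), NC = matrix(0.5, 2, 2),
                        M = 2L, p = 1L, n_eval = 10,
                        channel_names = c("a", "b")),
                   class = "connectivity_result")
  surr_hi <- array(3, dim = c(100, 2, 2))     # all surrogates above observed
  surr_lo <- array(1, dim = c(100, 2, 2))     # all below
  res <- surrogate_significance(obs, surr_lo, surr_hi, alpha = 0.05)
  expect_equal(res$p_LC[1, 2], 1 / 101)
  expect_equal(res$p_NC[1, 2], 1)
  expect_true(res$significant_LC[1, 2])
  expect_false(res$significant_NC[1, 2])
  expect_true(is.na(res$significant_LC[1, 1]))
  expect_error(surrogate_significance(obs, NULL, surr_hi), "required")
})

test_that("benchmark edges appear in the right component", {
  sim <- b1_sim(4000, seed = 1)
  set.seed(1)
  reg <- build_regressors(sim$series, 10)
  m <- fit_ncreann(reg, seed = NULL)
  conn <- decompose_connectivity(m, reg, eval_seed = NULL)
  lc <- conn$LC; diag(lc) <- -Inf
  expect_equal(which(lc == max(lc)), which(row(lc) == 2 & col(lc) == 1))
  expect_gt(conn$NC[3, 1], conn$NC[2, 1])
  expect_gt(conn$NC[3, 1], max(conn$NC[2, 3], conn$NC[1, 2], conn$NC[1, 3]))
  expect_true(all(conn$LC >= 0) && all(conn$NC >= 0))
})

test_that("linear connectivity matches least-squares MVAR coefficients", {
  sim <- simulate_nmvar(linear_mvar2(), 8000, seed = 4)
  reg <- build_regressors(sim$series, 2)
  set.seed(5)
  m <- fit_ncreann(reg, seed = NULL)
  conn <- decompose_connectivity(m, reg, eval_seed = NULL)
  ls <- qr.solve(cbind(1, reg$X), reg$Y)
  B <- abs(ls[-1, , drop = FALSE])
  LC_ls <- matrix(0, 3, 3)
  for (k in 1:2) LC_ls <- LC_ls + t(B[(k - 1) * 3 + 1:3, ])
  LC_ls <- LC_ls / 2
  # relative agreement on the true edges (1->2 at lag 1, 2->3 at lag 2)
  for (edge in list(c(2, 1), c(3, 2), c(1, 1), c(2, 2), c(3, 3))) {
    a <- conn$LC[edge[1], edge[2]]; b <- LC_ls[edge[1], edge[2]]
    expect_lt(abs(a - b) / b, 0.25)
  }
  # purely linear system: nonlinear component is a small fraction of the
  # true-edge linear weight
  true_lc <- c(conn$LC[2, 1], conn$LC[3, 2])
  expect_lte(median(conn$NC[row(conn$NC) != col(conn$NC)]),
             0.25 * median(true_lc))
})

test_that("the full estimator flags planted edges against surrogates", {
  sim <- b1_sim(4000, seed = 6)
  conn <- estimate_connectivity(sim$series, order = 10, n_surrogates = 20,
                                seed = 6)
  expect_lt(conn$p_LC[2, 1], 0.05)
  expect_lt(conn$p_NC[3, 1], 0.05)
  expect_equal(conn$n_surrogates, 20)
  expect_equal(dim(conn$surrogate_LC), c(20, 3, 3))
  # reproducibility of the entire estimate
  conn2 <- estimate_connectivity(sim$series, order = 10, n_surrogates = 20,
                                 seed = 6)
  expect_identical(conn$LC, conn2$LC)
  expect_identical(conn$p_NC, conn2$p_NC)
})

test_that("connectivity tables list every ordered off-diagonal pair", {
  sim <- b1_sim(2000, seed = 1)
  set.seed(2)
  reg <- build_regressors(sim$series, 4)
  m <- suppressWarnings(fit_ncreann(reg, folds = 2, seed = NULL))
  conn <- decompose_connectivity(m, reg)
  tab <- connectivity_table(conn, band = "alpha", condition = "nogo_congruent")
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$source != tab$target))
  expect_equal(tab$LC[tab$source == "x1" & tab$target == "x2"], conn$LC[2, 1])
})
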