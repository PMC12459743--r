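test_that("a zero-target mapping trains to zero output", {
  set.seed(1)
  X <- matrix(rnorm(600 * 4), 600, 4)
  reg <- structure(list(X = X, Y = matrix(0, 600, 2), M = 2L, p = 2L,
                        n = 600L, center = c(0, 0), scale = c(1, 1),
                        series = matrix(rnorm(10), 5, 2), trial_id = rep(1, 5),
                        channel_names = c("a", "b")),
                   class = "regressor_set")
  m <- suppressWarnings(fit_ncreann(reg, folds = 2, max_epochs = 100, seed = 2))
  expect_lt(mean(m$residuals^2), 1e-3)
})

test_that("the network matches a least-squares fit on purely linear data", {
  sim <- simulate_nmvar(linear_mvar2(), 6000, seed = 2)
  reg <- build_regressors(sim$series, order = 2)
  set.seed(3)
  n <- reg$n; itr <- sample(n, floor(0.9 * n)); ite <- setdiff(seq_len(n), itr)
  ls <- qr.solve(cbind(1, reg$X[itr, ]), reg$Y[itr, ])
  mse_ls <- mean((reg$Y[ite, ] - cbind(1, reg$X[ite, ]) %*% ls)^2)
  m <- fit_ncreann(reg, full_data = TRUE, seed = 3)
  mse_net <- mean((reg$Y[ite, ] - predict(m, reg$X[ite, ]))^2)
  expect_lt(mse_net, 1.1 * mse_ls)
})

test_that("training metrics are reported per fold with the split protocol", {
  sim <- b1_sim(2000, seed = 4)
  reg <- build_regressors(sim$series, order = 4)
  m <- suppressWarnings(fit_ncreann(reg, folds = 3, seed = 5))
  expect_equal(nrow(m$metrics), 3)
  expect_true(all(is.finite(m$metrics$mse_test)))
  expect_true(all(m$metrics$r2_test <= 1))
  expect_named(m$mean_metrics,
               c("mse_train", "mse_train_sd", "mse_test", "mse_test_sd",
                 "r2_train", "r2_train_sd", "r2_test", "r2_test_sd"))
  expect_gt(m$stop_epoch, 0)
})

test_that("fitting is reproducible under a fixed seed", {
  sim <- b1_sim(2000, seed = 4)
  reg <- build_regressors(sim$series, order = 4)
  m1 <- suppressWarnings(fit_ncreann(reg, folds = 2, seed = 11))
  m2 <- suppressWarnings(fit_ncreann(reg, folds = 2, seed = 11))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  c1 <- decompose_connectivity(m1, reg, eval_seed = 3)
  c2 <- decompose_connectivity(m2, reg, eval_seed = 3)
  expect_identical(c1$LC, c2$LC)
  expect_identical(c1$NC, c2$NC)
})

test_that("network Jacobian matches central finite differences", {
  sim <- b1_sim(2000, seed = 4)
  reg <- build_regressors(sim$series, order = 4)
  m <- suppressWarnings(fit_ncreann(reg, folds = 2, seed = 7))
  set.seed(8)
  D <- ncol(reg$X)
  for (r in 1:20) {
    x <- rnorm(D)
    J <- network_jacobian(m, x)
    eps <- 1e-5
    Jfd <- vapply(seq_len(D), function(k) {
      e <- numeric(D); e[k] <- eps
      as.numeric(predict(m, matrix(x + e, 1)) -
                   predict(m, matrix(x - e, 1))) / (2 * eps)
    }, numeric(m$M))
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-5)
  }
})

test_that("a null network yields zero connectivity", {
  sim <- b1_sim(2000, seed = 4)
  reg <- build_regressors(sim$series, order = 4)
  m <- suppressWarnings(fit_ncreann(reg, folds = 2, seed = 7))
  m$W2[] <- 0
  conn <- decompose_connectivity(m, reg, eval_seed = 1)
  expect_true(all(conn$LC == 0))
  expect_true(all(conn$NC == 0))
  m$M <- 5L
  expect_error(decompose_connectivity(m, reg), "M or p")
})
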