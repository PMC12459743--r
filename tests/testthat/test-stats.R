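mini_design <- function() {
  structure(data.frame(
    index = 1:8,
    block = rep(1, 8),
    trial_type = rep(c("Go", "Nogo"), each = 4),
    congruency = rep(c("congruent", "congruent", "incongruent", "incongruent"), 2),
    stimulus_side = rep("left", 8),
    correct_response = c(rep("left", 4), rep("none", 4)),
    iti_ms = 1500), class = c("task_design", "data.frame"))
}

test_that("response coding applies the window rules", {
  d <- mini_design()
  resp <- data.frame(
    trial_index = 1:8,
    response = c("left", "right", "none", "left", "none", "left", "none", "right"),
    rt_ms = c(400, 300, NA, 1800, NA, 1690, NA, 200))
  rec <- code_responses(d, resp)
  expect_equal(rec$outcome,
               c("hit", "error", "miss", "miss",
                 "correct_omission", "false_alarm", "correct_omission",
                 "false_alarm"))
  # late responses have their RT blanked (treated as no response)
  expect_true(is.na(rec$rt_ms[4]))
  expect_error(code_responses(d, data.frame(trial_index = 99,
                                            response = "left", rt_ms = 100)),
               "not in the design")
})

test_that("outcome counts always partition the design", {
  d <- generate_task_design(240, 0.75, 0.5, 2, seed = 31)
  rec <- simulate_behavior(d, seed = 32)
  n_go <- sum(d$trial_type == "Go")
  expect_equal(sum(rec$outcome %in% c("hit", "error", "miss")), n_go)
  expect_equal(sum(rec$outcome %in% c("correct_omission", "false_alarm")),
               nrow(d) - n_go)
})

test_that("accuracy table counts cells and flags empty ones", {
  d <- mini_design()
  resp <- data.frame(trial_index = 1:8,
                     response = c(rep("left", 4), rep("none", 4)),
                     rt_ms = c(rep(500, 4), rep(NA, 4)))
  acc <- accuracy_table(code_responses(d, resp), d)
  expect_equal(acc$accuracy, rep(1, 4))
  # all Go responses missing
  resp2 <- data.frame(trial_index = 1:8, response = "none", rt_ms = NA_real_)
  acc2 <- accuracy_table(code_responses(d, resp2), d)
  expect_equal(acc2$accuracy[acc2$trial_type == "Go"], c(0, 0))
  # hand count: 1 of 2 Nogo congruent correct
  resp3 <- resp
  resp3$response[5] <- "left"; resp3$rt_ms[5] <- 600
  acc3 <- accuracy_table(code_responses(d, resp3), d)
  expect_equal(acc3$accuracy[acc3$trial_type == "Nogo" &
                               acc3$congruency == "congruent"], 0.5)
})

test_that("Simon Nogo effect is the congruent minus incongruent difference", {
  acc <- data.frame(trial_type = c("Nogo", "Nogo"),
                    congruency = c("congruent", "incongruent"),
                    n = c(100, 100), n_correct = c(85, 91),
                    accuracy = c(0.85, 0.91), undefined = FALSE)
  expect_equal(simon_nogo_effect(acc), -0.06)
  acc$accuracy <- c(0.9, 0.9)
  expect_equal(simon_nogo_effect(acc), 0)
  acc$undefined[1] <- TRUE
  expect_warning(out <- simon_nogo_effect(acc), "undefined")
  expect_true(is.na(out))
})

test_that("group difference in the Simon Nogo effect is recoverable by simulation", {
  # smaller-magnitude effect in one parameter set than the other, n = 60/group
  p_small <- c(go_congruent = 0.97, go_incongruent = 0.93,
               nogo_congruent = 0.88, nogo_incongruent = 0.90)
  p_large <- c(go_congruent = 0.97, go_incongruent = 0.93,
               nogo_congruent = 0.82, nogo_incongruent = 0.92)
  d <- generate_task_design(seed = 41)
  recover <- vapply(1:20, function(s) {
    eff <- vapply(list(p_small, p_large), function(p) {
      mean(vapply(1:3, function(k) {
        rec <- simulate_behavior(d, p_correct = p, seed = s * 100 + k)
        simon_nogo_effect(accuracy_table(rec, d))
      }, numeric(1)))
    }, numeric(1))
    abs(eff[1]) < abs(eff[2])
  }, logical(1))
  expect_gte(mean(recover), 0.95)
})

test_that("direction asymmetry uses a paired signed-rank test", {
  expect_equal(direction_asymmetry_test(rep(1, 10), rep(1, 10))$p, 1)
  res <- direction_asymmetry_test(2:21 + 1, 2:21)
  expect_lt(res$p, 0.001)
  expect_equal(res$direction, "ij")
  expect_true(res$significant)
  expect_error(direction_asymmetry_test(1:5, 2:6), "at least 6")
})

test_that("direction test holds its nominal size on exchangeable pairs", {
  # exact effective size of the two-sided signed-rank test at n = 12
  # (discrete statistic: the attainable level is slightly below 0.05)
  n <- 12
  w <- 0:(n * (n + 1) / 2)
  p2 <- pmin(1, 2 * pmin(psignrank(w, n), 1 - psignrank(w - 1, n)))
  eff_alpha <- sum(dsignrank(w, n) * (p2 < 0.05))
  set.seed(55)
  reps <- 400
  rejections <- vapply(seq_len(reps), function(i) {
    a <- rnorm(n); b <- rnorm(n)
    direction_asymmetry_test(a, b)$significant
  }, logical(1))
  ci <- qbinom(c(0.025, 0.975), reps, eff_alpha)
  expect_gte(sum(rejections), ci[1])
  expect_lte(sum(rejections), ci[2])
})

test_that("network strength averages off-diagonal entries", {
  m <- matrix(3, 4, 4)
  expect_equal(network_strength(m), 3)
  m2 <- matrix(c(9, 2, 7, 9), 2, 2)   # diagonal 9s ignored
  expect_equal(network_strength(m2), (2 + 7) / 2)
  set.seed(6)
  r <- matrix(runif(25), 5, 5)
  expect_equal(network_strength(r), mean(r[row(r) != col(r)]))
  expect_equal(network_strength(r, include_self = TRUE), mean(r))
})

test_that("strength comparisons use the appropriate rank tests", {
  expect_equal(compare_strength(1:10, 1:10, paired = TRUE)$p, 1)
  set.seed(7)
  a <- rnorm(30); b <- rnorm(30) + 2
  res <- compare_strength(a, b, paired = FALSE)
  expect_lt(res$p, 0.01)
  expect_match(res$method, "Wilcoxon")
  expect_error(compare_strength(1:2, 1:2), "at least 3")
  expect_error(compare_strength(1:5, 1:4, paired = TRUE), "equal lengths")
})
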