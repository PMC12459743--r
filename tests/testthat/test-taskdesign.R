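test_that("task design cell counts are exact for valid configurations", {
  d <- generate_task_design(720, 0.7, 0.5, 6, c(1300, 1700), seed = 3)
  expect_equal(sum(d$trial_type == "Go"), 504)
  expect_equal(sum(d$trial_type == "Nogo"), 216)
  expect_equal(as.integer(table(d$block)), rep(120L, 6))
  per_block <- table(d$block, d$trial_type, d$congruency)
  expect_true(all(per_block[, "Nogo", "congruent"] == 18))
  expect_true(all(per_block[, "Go", "incongruent"] == 42))
  expect_equal(sum(d$trial_type == "Nogo" & d$congruency == "congruent"), 108)

  # closed-form products hold for an arbitrary valid configuration
  d2 <- generate_task_design(40, 0.5, 0.5, 2, c(1300, 1700), seed = 7)
  tab <- table(d2$trial_type, d2$congruency)
  expect_true(all(tab == 10))
  expect_true(all(table(d2$block) == 20))
})

test_that("task design handles edge and error cases", {
  expect_equal(nrow(generate_task_design(0, 0.7, 0.5, 1, c(1300, 1700), 0)), 0)
  # 100 trials over 6 blocks: not divisible
  expect_error(generate_task_design(100, 0.7, 0.5, 6), "divisible")
  # divisible, but Nogo-congruent per block is 120*0.3*0.45 = 16.2
  expect_error(generate_task_design(720, 0.7, 0.45, 6), "congruent")
})

test_that("task design invariants: ITI range, Nogo responses, determinism", {
  d <- generate_task_design(seed = 11)
  expect_true(all(d$iti_ms >= 1300 & d$iti_ms <= 1700))
  expect_true(all(d$correct_response[d$trial_type == "Nogo"] == "none"))
  expect_true(all(d$correct_response[d$trial_type == "Go"] %in% c("left", "right")))
  # congruent = stimulus side matches the response hand
  go <- d[d$trial_type == "Go", ]
  expect_equal(go$congruency == "congruent",
               go$stimulus_side == go$correct_response)
  expect_identical(d, generate_task_design(seed = 11))
  expect_false(identical(d$trial_type, generate_task_design(seed = 12)$trial_type))
})

test_that("task design round-trips through CSV", {
  d <- generate_task_design(120, 0.5, 0.5, 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_task_design(d, path)
  d2 <- read_task_design(path)
  expect_equal(as.data.frame(d), as.data.frame(d2), tolerance = 1e-12)
})

test_that("behavioral accuracy follows the per-cell binomial model", {
  d <- generate_task_design(720, 0.7, 0.5, 6, seed = 2)
  # degenerate probability: no false alarms possible in that cell
  rec <- simulate_behavior(d, p_correct = c(go_congruent = 0.95,
                                            go_incongruent = 0.9,
                                            nogo_congruent = 1.0,
                                            nogo_incongruent = 0.8),
                           seed = 9)
  nogo_c <- d$index[d$trial_type == "Nogo" & d$congruency == "congruent"]
  expect_true(all(rec$outcome[rec$trial_index %in% nogo_c] == "correct_omission"))

  # observed rate within the exact central 99% binomial interval (n = 108)
  rec2 <- simulate_behavior(d, p_correct = c(go_congruent = 0.95,
                                             go_incongruent = 0.9,
                                             nogo_congruent = 0.85,
                                             nogo_incongruent = 0.9),
                           seed = 11)
  k <- sum(rec2$outcome[rec2$trial_index %in% nogo_c] == "correct_omission")
  expect_gte(k, qbinom(0.005, 108, 0.85))
  expect_lte(k, qbinom(0.995, 108, 0.85))
})

test_that("Simon shift moves incongruent Go reaction times", {
  d <- generate_task_design(720, 0.7, 0.5, 6, seed = 4)
  rec <- simulate_behavior(d, rt_model = list(mean_ms = 450, sd_ms = 100,
                                              simon_shift_ms = 30), seed = 21)
  m <- merge(as.data.frame(d), rec, by.x = "index", by.y = "trial_index")
  hit <- m[m$outcome == "hit", ]
  rt_c <- hit$rt_ms[hit$congruency == "congruent"]
  rt_i <- hit$rt_ms[hit$congruency == "incongruent"]
  se <- sqrt(var(rt_c) / length(rt_c) + var(rt_i) / length(rt_i))
  expect_lt(abs((mean(rt_i) - mean(rt_c)) - 30), 3 * se)
})

test_that("behavior simulation rejects unknown condition keys and is reproducible", {
  d <- generate_task_design(40, 0.5, 0.5, 2, seed = 1)
  expect_error(simulate_behavior(d, p_correct = c(go_left = 1)), "unknown condition")
  r1 <- simulate_behavior(d, seed = 5)
  r2 <- simulate_behavior(d, seed = 5)
  expect_identical(r1, r2)
})
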