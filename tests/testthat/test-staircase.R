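test_that("the 3-down/1-up update rule follows the transformed up-down convention", {
  cfg <- staircase_config(45, "decrease")
  s <- staircase_init(cfg)
  expect_equal(s$current_delta, 2.5)

  # incorrect: one step up, counter resets
  s1 <- staircase_update(s, FALSE, cfg)
  expect_equal(s1$current_delta, 3.0)
  expect_equal(s1$consecutive_correct, 0L)

  # two corrects banked, third correct: one step down, counter resets
  s2 <- s; s2$consecutive_correct <- 2L
  s2 <- staircase_update(s2, TRUE, cfg)
  expect_equal(s2$current_delta, 2.0)
  expect_equal(s2$consecutive_correct, 0L)

  # first correct: no step yet
  s3 <- staircase_update(s, TRUE, cfg)
  expect_equal(s3$current_delta, 2.5)
  expect_equal(s3$consecutive_correct, 1L)

  # updating a finished block is an error
  s4 <- s; s4$trial_index <- cfg$n_trials
  expect_error(staircase_update(s4, TRUE, cfg), class = "staircase_complete_error")
})

test_that("a near-perfect observer rides the staircase down to the smallest step", {
  cfg <- staircase_config(45, "increase")
  set.seed(11)
  log <- run_block(cfg, sharp_obs())
  expect_equal(nrow(log), 30L)
  # deterministic descent: one down-step every 3 trials until the 0.5 floor
  expected <- pmax(rep(seq(2.5, by = -0.5, length.out = 10), each = 3), 0.5)
  expect_equal(log$delta_c, expected)
  expect_true(all(log$correct))
  expect_false(attr(log, "bound_violation"))
})

test_that("a guessing observer drifts into the ceiling clamp and is flagged", {
  cfg <- staircase_config(45, "increase") # headroom only 2.5 degC above start
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    attr(run_block(cfg, guessing_obs()), "bound_violation")
  }, logical(1))
  expect_true(all(hits))
  set.seed(1)
  log <- run_block(cfg, guessing_obs())
  expect_true(any(log$clamped))
  expect_true(max(log$delta_c) <= 5) # 45 + delta never exceeds 50
})

test_that("presented deltas stay on the step grid anchored at the start", {
  obs <- convex_obs(lapse = 0.02)
  for (s in 1:5) {
    set.seed(s)
    log <- run_block(staircase_config(45, "decrease"), obs)
    offsets <- (log$delta_c - 2.5) / 0.5
    expect_equal(offsets, round(offsets))
    expect_true(all(log$delta_c >= 0.5))
  }
})

test_that("estimate_threshold averages the last 20 deltas, ignoring the first 10", {
  cfg <- staircase_config(45, "increase")
  mk_log <- function(deltas) {
    structure(data.frame(trial = seq_along(deltas), interval_of_change = 1L,
                         delta_c = deltas, response_interval = 1L,
                         correct = TRUE, confidence = 1L, clamped = FALSE),
              class = c("block_log", "data.frame"))
  }
  expect_equal(estimate_threshold(mk_log(c(runif(10), rep(2, 20))), cfg)$value, 2)

  # spreadsheet oracle: a listed 30-delta sequence, mean of entries 11-30
  # computed by independent arithmetic (cumulative sums)
  deltas <- c(2.5, 3.0, 3.5, 3.0, 3.0, 3.0, 2.5, 3.0, 2.5, 2.5,
              2.0, 2.0, 2.0, 2.5, 2.5, 2.5, 2.0, 2.0, 2.0, 1.5,
              2.0, 2.0, 2.0, 1.5, 1.5, 1.5, 2.0, 1.5, 1.5, 1.5)
  oracle <- (sum(cumsum(deltas)[30] - cumsum(deltas)[10])) / 20
  est <- estimate_threshold(mk_log(deltas), cfg)
  expect_equal(est$value, oracle)
  expect_equal(est$n_retained, 20L)

  # permuting the discarded trials changes nothing
  perm <- deltas; perm[1:10] <- perm[sample(10)]
  expect_equal(estimate_threshold(mk_log(perm), cfg)$value, est$value)

  expect_error(estimate_threshold(mk_log(deltas[1:25]), cfg),
               class = "incomplete_block_error")
})

test_that("convergence_accuracy solves the k-down balance condition", {
  expect_equal(convergence_accuracy(1), 0.5)
  expect_equal(convergence_accuracy(2), sqrt(0.5))
  expect_equal(convergence_accuracy(3), 0.79370053, tolerance = 1e-7)
})

test_that("theoretical_threshold inverts the psychometric function", {
  # closed form for the linear lapse-free observer:
  # delta* = sqrt(2) * sigma * qnorm(0.5^(1/3))
  lin <- linear_obs(sigma = 1.5)
  thr <- theoretical_threshold(lin, "increase", 45)
  expect_equal(thr, sqrt(2) * 1.5 * qnorm(0.5^(1 / 3)), tolerance = 1e-3)
  # symmetry for the linear transducer
  expect_equal(theoretical_threshold(lin, "decrease", 45), thr, tolerance = 2e-4)

  # grid-scan oracle at 0.01 degC resolution
  cvx <- convex_obs(lapse = 0.02)
  thr2 <- theoretical_threshold(cvx, "decrease", 45)
  grid <- seq(0.01, 10, by = 0.01)
  pg <- prob_correct_detection(grid, "decrease", 45, cvx)
  oracle <- grid[which(pg >= convergence_accuracy(3))[1]]
  expect_lt(abs(thr2 - oracle), 0.01 + 1e-9)

  # unattainable accuracy signals no solution
  expect_warning(
    out <- theoretical_threshold(guessing_obs(), "increase", 45),
    class = "no_solution_warning")
  expect_true(is.na(out))
})

test_that("discrimination blocks hold the reference fixed and stay above it", {
  obs <- convex_obs(lapse = 0.02)
  cfg <- staircase_config(45, "decrease", mode = "discrimination",
                          reference_delta = 1.6)
  set.seed(21)
  log <- run_block(cfg, obs)
  expect_equal(nrow(log), 30L)
  expect_equal(log$delta_c[1], 1.6 + 2.5)
  expect_true(all(log$delta_c >= 1.6 + 0.5 - 1e-9))
})

test_that("block logs round-trip through CSV losslessly", {
  set.seed(31)
  log <- run_block(staircase_config(45, "decrease"), convex_obs(lapse = 0.02))
  path <- withr::local_tempfile(fileext = ".csv")
  write_block_log(log, path)
  back <- read_block_log(path)
  expect_equal(as.data.frame(back), as.data.frame(log),
               ignore_attr = TRUE)
})
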