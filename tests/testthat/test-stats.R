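test_that("paired_t matches first principles and the reference implementation", {
  # 5-pair toy sample: long-hand computation
  x <- c(3.2, 2.9, 4.1, 3.3, 3.8)
  y <- c(1.5, 2.2, 2.0, 2.6, 1.9)
  d <- x - y
  m <- sum(d) / 5
  s <- sqrt(sum((d - m)^2) / 4)
  out <- paired_t(x, y)
  expect_equal(out$t, m / (s / sqrt(5)))
  expect_equal(out$dz, m / s)
  expect_equal(out$df, 4L)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$p, ref$p.value)

  # identity t = dz * sqrt(n) to machine precision
  set.seed(101)
  a <- rnorm(12); b <- rnorm(12)
  o <- paired_t(a, b)
  expect_equal(o$t, o$dz * sqrt(12), tolerance = 1e-12)

  # mean-zero differences: t ~ 0, p ~ 1
  o0 <- paired_t(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(o0$t, 0)
  expect_equal(o0$p, 1)

  # identical vectors have zero-variance differences: degenerate signal
  expect_error(paired_t(a, a), class = "degenerate_sample")
  expect_error(paired_t(1:3, 1:4), class = "invalid_sample")
})

test_that("paired_t p-values are uniform under the null", {
  set.seed(202)
  p <- replicate(2000, paired_t(rnorm(16), rnorm(16))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

make_2x2 <- function(n, fx = 0, fy = 0, fxy = 0, sd_s = 1, sd_e = 1, seed = 1) {
  set.seed(seed)
  g <- expand.grid(participant = seq_len(n), a = c("a1", "a2"), b = c("b1", "b2"))
  subj <- rnorm(n, 0, sd_s)
  g$value <- subj[g$participant] +
    fx * (g$a == "a2") + fy * (g$b == "b2") +
    fxy * (g$a == "a2") * (g$b == "b2") + rnorm(nrow(g), 0, sd_e)
  g
}

test_that("rm_anova_2x2 matches aov() and the squared-paired-t identity", {
  g <- make_2x2(10, fx = 1.2, fy = 0.4, fxy = 0.6, seed = 11)
  res <- rm_anova_2x2(g)

  # independent oracle: base R aov with the within-subject error stratum
  fit <- stats::aov(value ~ a * b + Error(factor(participant) / (a * b)), data = g)
  sm <- summary(fit)
  f_aov <- c(a = sm[["Error: factor(participant):a"]][[1]]["a", "F value"],
             b = sm[["Error: factor(participant):b"]][[1]]["b", "F value"],
             ab = sm[["Error: factor(participant):a:b"]][[1]]["a:b", "F value"])
  expect_equal(res$effects$F, unname(f_aov), tolerance = 1e-10)
  expect_equal(res$effects$df_den, rep(9L, 3))

  # each effect's F is the square of the paired t on difference scores
  m <- tapply(g$value, list(g$participant, interaction(g$a, g$b)), mean)
  t_a <- paired_t((m[, "a2.b1"] + m[, "a2.b2"]) / 2,
                  (m[, "a1.b1"] + m[, "a1.b2"]) / 2)
  t_b <- paired_t((m[, "a1.b2"] + m[, "a2.b2"]) / 2,
                  (m[, "a1.b1"] + m[, "a2.b1"]) / 2)
  t_ab <- paired_t(m[, "a2.b2"] - m[, "a1.b2"], m[, "a2.b1"] - m[, "a1.b1"])
  expect_equal(res$effects$F,
               c(t_a$t^2, t_b$t^2, t_ab$t^2), tolerance = 1e-10)

  expect_true(all(res$effects$partial_eta_sq >= 0 & res$effects$partial_eta_sq <= 1))
})

test_that("rm_anova_2x2 handles degenerate and invalid inputs", {
  # all cells equal within each participant: all effects vanish
  g <- expand.grid(participant = 1:5, a = c("x", "y"), b = c("u", "v"))
  g$value <- g$participant * 1.5
  res <- rm_anova_2x2(g)
  expect_equal(res$effects$F, c(0, 0, 0))
  expect_equal(res$effects$p, c(1, 1, 1))

  expect_error(rm_anova_2x2(g[-1, ]), class = "invalid_design")
  g3 <- g; g3$a <- as.character(g3$a); g3$a[1:5] <- "z"
  expect_error(rm_anova_2x2(g3), class = "invalid_design")
})

test_that("required_sample_size reproduces the design's recruitment target", {
  # dz = 0.76, two-sided alpha 0.05, power 0.80 -> 16 participants
  expect_identical(required_sample_size(0.76), 16L)

  # defining property: the minimum crosses the target between n-1 and n
  n <- required_sample_size(0.76)
  expect_lt(power_paired_t(n - 1, 0.76), 0.80)
  expect_gte(power_paired_t(n, 0.76), 0.80)

  # normal-approximation bracket: z-test n is a slight underestimate
  n_norm <- ceiling(((qnorm(0.975) + qnorm(0.80)) / 0.76)^2)
  expect_true(n >= n_norm && n <= n_norm + 3)

  expect_error(required_sample_size(0.01, max_n = 100),
               class = "power_unattainable")
})

test_that("confidence_summary cross-tabulates descriptively", {
  toy <- data.frame(
    task = rep(c("detection", "discrimination"), each = 4),
    direction = rep(c("increase", "increase", "decrease", "decrease"), 2),
    correct = rep(c(TRUE, FALSE), 4),
    confidence = c(2, 1, 2, 2, 1, 1, 2, 1))
  out <- confidence_summary(toy)
  # hand tally: detection/increase/TRUE -> conf 2 -> confident
  g <- function(task, dir, cor) out$prop_confident[out$task == task &
    out$direction == dir & out$correct == cor]
  expect_equal(g("detection", "increase", TRUE), 1.0)
  expect_equal(g("detection", "increase", FALSE), 0.0)
  expect_equal(g("discrimination", "decrease", TRUE), 1.0)
  expect_equal(sum(out$n), 8)

  # invariant to row order
  out2 <- confidence_summary(toy[sample(nrow(toy)), ])
  expect_equal(out2, out)

  # all-confident logs rate 1.0 everywhere
  toy$confidence <- 2
  expect_true(all(confidence_summary(toy)$prop_confident == 1))

  # 4-point scale reports mean level
  toy$confidence <- rep(c(4, 2), 4)
  out4 <- confidence_summary(toy, scale = "four_point")
  expect_true(all(out4$mean_confidence %in% c(4, 2)))
})
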