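#' Paired-samples t test with Cohen's d_z
#'
#' First-principles paired t: with differences `d = x - y`,
#' `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p from the t distribution with
#' `n - 1` df, and the standardized paired effect size
#' `d_z = mean(d) / sd(d)` (so `t = d_z * sqrt(n)`).
#'
#' @param x,y paired measurements, one pair per participant; no missing pairs.
#' @return a list: `t`, `df`, `p`, `dz`, `mean_diff`, `n`.
#' @export
#' @examples
#' paired_t(c(3.2, 2.8, 4.1, 3.6), c(1.5, 1.9, 2.2, 1.4))
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must be paired", "invalid_sample")
  if (anyNA(x) || anyNA(y)) stop_invalid("missing pairs are not allowed", "invalid_sample")
  n <- length(x)
  if (n < 2) stop_invalid("need at least 2 pairs", "invalid_sample")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop_invalid("zero variance of differences", "degenerate_sample")
  tval <- mean(d) / (sd_d / sqrt(n))
  list(t = tval, df = n - 1L,
       p = 2 * stats::pt(abs(tval), n - 1L, lower.tail = FALSE),
       dz = mean(d) / sd_d, mean_diff = mean(d), n = n)
}

#' 2 x 2 within-subject (repeated measures) ANOVA
#'
#' Standard within-subject sum-of-squares decomposition for a fully crossed
#' 2 x 2 design with one observation per participant per cell. Each effect
#' (A, B, A:B) is tested against its own subject-by-effect interaction error
#' with `F(1, n - 1)`; the effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error_effect)`. With two-level factors each F
#' equals the square of the paired t on the corresponding difference scores,
#' and sphericity is not an issue.
#'
#' @param data long-format data frame, one row per participant x cell.
#' @param participant,a,b,value column names for participant id, factor A,
#'   factor B, and the response.
#' @return a list of class `anova_2x2`: `effects` (data frame with columns
#'   `effect`, `F`, `df_num`, `df_den`, `p`, `partial_eta_sq`), `grand_mean`,
#'   `cell_means` (2 x 2 matrix).
#' @export
rm_anova_2x2 <- function(data, participant = "participant", a = "a", b = "b",
                         value = "value") {
  pid <- factor(data[[participant]])
  fa <- factor(data[[a]]); fb <- factor(data[[b]])
  y <- data[[value]]
  if (nlevels(fa) != 2L || nlevels(fb) != 2L) {
    stop_invalid("both factors must have exactly 2 levels", "invalid_design")
  }
  tab <- table(pid, fa, fb)
  if (any(tab != 1L)) stop_invalid("incomplete cells: need one observation per participant per cell", "invalid_design")
  n <- nlevels(pid)
  if (n < 2) stop_invalid("need at least 2 participants", "invalid_design")

  gm <- mean(y)
  is <- as.integer(pid); ia <- as.integer(fa); ib <- as.integer(fb)
  m_s <- tapply(y, pid, mean)                 # subject means
  m_a <- tapply(y, fa, mean)                  # marginal means of A
  m_b <- tapply(y, fb, mean)
  m_ab <- tapply(y, list(fa, fb), mean)       # cell means
  m_sa <- tapply(y, list(pid, fa), mean)
  m_sb <- tapply(y, list(pid, fb), mean)

  ss_a <- 2 * n * sum((m_a - gm)^2)
  ss_b <- 2 * n * sum((m_b - gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  # per-row sums count every (subject, level) cell b (resp. a) = 2 times,
  # which is exactly the SS_SA = 2 * sum over cells weighting
  ss_sa <- sum((m_sa[cbind(is, ia)] - m_s[is] - m_a[ia] + gm)^2)
  ss_sb <- sum((m_sb[cbind(is, ib)] - m_s[is] - m_b[ib] + gm)^2)
  # three-way residual (subject x A x B), the error term for the interaction
  r3 <- y - m_sa[cbind(is, ia)] - m_sb[cbind(is, ib)] - m_ab[cbind(ia, ib)] +
    m_s[is] + m_a[ia] + m_b[ib] - gm
  ss_sab <- sum(r3^2)

  eff <- function(name, ss_e, ss_err) {
    # a zero effect sum of squares is a zero effect even if its error term
    # also vanishes (e.g. all cells equal within every participant)
    if (ss_e <= .Machine$double.eps * sum(y^2)) {
      return(data.frame(effect = name, F = 0, df_num = 1L, df_den = n - 1L,
                        p = 1, partial_eta_sq = 0))
    }
    Fv <- (ss_e / 1) / (ss_err / (n - 1))
    data.frame(effect = name, F = Fv, df_num = 1L, df_den = n - 1L,
               p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
               partial_eta_sq = ss_e / (ss_e + ss_err))
  }
  effects <- rbind(eff("a", ss_a, ss_sa), eff("b", ss_b, ss_sb),
                   eff("a:b", ss_ab, ss_sab))
  rownames(effects) <- NULL
  structure(list(effects = effects, grand_mean = gm, cell_means = m_ab,
                 n = n), class = "anova_2x2")
}

#' Power of the two-sided paired t test
#'
#' Exact noncentral-t power: with effect size `dz` and `n` pairs the test
#' statistic follows a noncentral t with `n - 1` df and noncentrality
#' `dz * sqrt(n)`.
#'
#' @param n number of pairs.
#' @param dz standardized paired effect size (> 0).
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
power_paired_t <- function(n, dz, alpha = 0.05) {
  stopifnot(n >= 2, dz > 0, alpha > 0, alpha < 1)
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- dz * sqrt(n)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}

#' Minimal sample size for a paired design
#'
#' Smallest `n` such that the two-sided paired t test at level `alpha` has
#' power at least `target_power` for effect size `dz`, by exact noncentral-t
#' evaluation (power is increasing in `n`, so a linear scan from `n = 2`
#' terminates at the first crossing).
#'
#' @param dz standardized paired effect size (> 0).
#' @param alpha two-sided significance level; default 0.05.
#' @param target_power required power; default 0.80.
#' @param max_n give up beyond this `n`.
#' @return the minimal integer `n`.
#' @export
#' @examples
#' required_sample_size(0.76) # 16
required_sample_size <- function(dz, alpha = 0.05, target_power = 0.80,
                                 max_n = 10000L) {
  stopifnot(dz > 0, alpha > 0, alpha < 1, target_power > 0, target_power < 1)
  for (n in 2:max_n) {
    if (power_paired_t(n, dz, alpha) >= target_power) return(as.integer(n))
  }
  stop_invalid(sprintf("required n exceeds max_n = %d", max_n), "power_unattainable")
}

#' Descriptive confidence summary from block logs
#'
#' Cross-tabulates confidence by task, direction and trial accuracy from
#' pooled block logs: for the binary scale (levels 1 = guessing,
#' 2 = confident) the proportion confident; for the 4-point scale the mean
#' level. Purely descriptive; no inferential model is fitted.
#'
#' @param logs a data frame of pooled trial rows with columns `task`,
#'   `direction`, `correct`, `confidence` (integer levels starting at 1).
#' @param scale `"binary"` or `"four_point"`.
#' @return data frame with columns `task`, `direction`, `correct`, `n`, and
#'   `prop_confident` (binary) or `mean_confidence` (four_point).
#' @export
confidence_summary <- function(logs, scale = c("binary", "four_point")) {
  scale <- match.arg(scale)
  stopifnot(all(c("task", "direction", "correct", "confidence") %in% names(logs)))
  key <- list(task = logs$task, direction = logs$direction, correct = logs$correct)
  agg <- stats::aggregate(logs$confidence, by = key, FUN = function(v) {
    if (scale == "binary") mean(v >= 2) else mean(v)
  })
  cnt <- stats::aggregate(logs$confidence, by = key, FUN = length)
  out <- agg
  out$n <- cnt$x
  names(out)[names(out) == "x"] <-
    if (scale == "binary") "prop_confident" else "mean_confidence"
  out <- out[order(out$task, out$direction, out$correct),
             c("task", "direction", "correct", "n",
               if (scale == "binary") "prop_confident" else "mean_confidence")]
  rownames(out) <- NULL
  out
}
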