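# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid lm/t.test/cor.test/aov.

# Simple linear regression via explicit normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       rss = sum(res^2))
}

# Paired t-test from hand-summed formulas.
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s2 <- sum((d - m)^2) / (n - 1)
  t_val <- m / sqrt(s2 / n)
  list(t = t_val, df = n - 1,
       p = 2 * stats::pt(-abs(t_val), n - 1),
       d = m / sqrt(s2))
}

# Pearson r from raw covariance sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t_val <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t_val), n - 2))
}

# Fully within-subject two-factor ANOVA by explicit sums-of-squares
# decomposition: each effect tested against its own subject interaction.
rm_anova_oracle <- function(df) {
  y <- df$value
  s <- factor(df$subject); a <- factor(df$a); b <- factor(df$b)
  n <- nlevels(s); p <- nlevels(a); q <- nlevels(b)
  g <- mean(y)
  m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_s <- tapply(y, s, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_as <- tapply(y, list(a, s), mean)
  m_bs <- tapply(y, list(b, s), mean)

  ss_a <- n * q * sum((m_a - g)^2)
  ss_b <- n * p * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - matrix(m_a, p, q) -
                      matrix(m_b, p, q, byrow = TRUE) + g)^2)
  ss_as <- q * sum((m_as - matrix(m_a, p, n) -
                      matrix(m_s, p, n, byrow = TRUE) + g)^2)
  ss_bs <- p * sum((m_bs - matrix(m_b, q, n) -
                      matrix(m_s, q, n, byrow = TRUE) + g)^2)
  ss_s <- p * q * sum((m_s - g)^2)
  ss_tot <- sum((y - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs

  f_of <- function(ss_eff, df_eff, ss_err, df_err) {
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  list(
    F_a = f_of(ss_a, p - 1, ss_as, (p - 1) * (n - 1)),
    F_b = f_of(ss_b, q - 1, ss_bs, (q - 1) * (n - 1)),
    F_ab = f_of(ss_ab, (p - 1) * (q - 1), ss_abs, (p - 1) * (q - 1) * (n - 1))
  )
}

# Build a minimal clean trial tibble by hand (bypassing the generator).
make_trials <- function(trial_type, rotation, hand, judged,
                        side = rep_len(c("left", "right"), length(hand)),
                        condition = "Dyn", participant = "P01") {
  cursor <- hand + rotation
  if (identical(trial_type, "UniHand")) cursor <- rep(NA_real_, length(hand))
  tibble::tibble(
    participant_id = participant,
    condition = condition,
    trial_type = trial_type,
    rotation_deg = rotation,
    instructed_direction_deg = 0,
    true_hand_angle_deg = hand,
    true_cursor_angle_deg = cursor,
    judged_angle_deg = judged,
    marker_start_side = side,
    ring_drift_deg = 0,
    direction_deviation_deg = 0,
    outward_duration_s = 1.2,
    dwell_duration_s = 0.5,
    outlier_injected = FALSE,
    outlier_criterion = 0L
  )
}

# Default rotation grid repeated over n repetitions.
grid_rotations <- function(n_rep = 10) {
  rep(seq(-17.5, 17.5, by = 5), n_rep)
}
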