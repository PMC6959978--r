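# Independent oracles used across tests. These deliberately avoid the
# package's own code paths wherever they check one.

# Brute-force Pearson chi-square statistic.
pearson_brute <- function(observed, expected_proportions) {
  e <- sum(observed) * expected_proportions
  sum((observed - e)^2 / e)
}

# Brute-force division angle: rotate both points and the axis by the same
# angle, then take the acute angle from slopes via atan (independent of the
# package's atan2 folding path).
division_angle_brute <- function(d1, d2, bm, rot_deg = 0) {
  r <- rot_deg * pi / 180
  R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  d1 <- as.numeric(R %*% d1); d2 <- as.numeric(R %*% d2)
  bm <- as.numeric(R %*% bm)
  v <- d2 - d1
  ang <- function(w) atan2(w[2], w[1])
  raw <- abs(ang(v) - ang(bm)) * 180 / pi
  raw <- raw %% 180
  min(raw, 180 - raw)
}

# Draw folded two-component Gaussian mixture angles (bimodal pool).
rbimodal <- function(n, mu = c(10, 80), sd = 5) {
  comp <- sample(1:2, n, replace = TRUE)
  x <- rnorm(n, mean = mu[comp], sd = sd) %% 180
  ifelse(x > 90, 180 - x, x)
}

# Closed-form two-step trajectory (relaxation + independent frame noise),
# written independently of simulate_cohort, for settling-time oracles.
trajectory_oracle <- function(phi, target, tau = 10, sigma = 1.5,
                              t_grid = seq(0, 60, by = 5)) {
  det <- target + (phi - target) * exp(-t_grid / tau)
  noise <- c(0, rnorm(length(t_grid) - 1, sd = sigma))
  x <- (det + noise) %% 180
  ifelse(x > 90, 180 - x, x)
}
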