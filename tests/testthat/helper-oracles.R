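# Independent brute-force oracles. These transcribe textbook definitions
# directly (normal equations, order-statistic quantiles, elementwise sums)
# and never call the package functions they check.

# Type-7 quantile: linear interpolation between order statistics.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_iqr_mask <- function(x, k = 1.5) {
  q1 <- oracle_quantile(x, 0.25)
  q3 <- oracle_quantile(x, 0.75)
  x < q1 - k * (q3 - q1) | x > q3 + k * (q3 - q1)
}

# OLS by explicit normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  b1 <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  b0 <- (sy - b1 * sx) / n
  c(intercept = b0, slope = b1)
}

oracle_rto_slope <- function(x, y) sum(x * y) / sum(x^2)

oracle_metrics <- function(obs, est) {
  n <- length(obs)
  list(
    rmse = sqrt(sum((est - obs)^2) / n),
    mae = sum(abs(est - obs)) / n,
    rel_err_pct = abs(sum(est - obs)) / sum(obs) * 100
  )
}

# Two-sided t-test p-value for the OLS intercept, from first principles.
oracle_intercept_p <- function(x, y) {
  b <- oracle_ols(x, y)
  res <- y - b["intercept"] - b["slope"] * x
  n <- length(x)
  s2 <- sum(res^2) / (n - 2)
  se_b0 <- sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2)))
  2 * stats::pt(-abs(b["intercept"] / se_b0), df = n - 2)
}

# A small hand-built analysis-ready day: 9 hourly records, 10:00-18:00.
nine_hour_fixture <- function() {
  hours <- 10:18
  data.frame(
    timestamp = as_clock_time(sprintf("2021-07-08 %02d:00:00", hours)),
    t_air_c = seq(24, 36, length.out = 9),
    rh_pct = seq(60, 28, length.out = 9),
    rn_mj_m2_h = c(1.2, 1.7, 2.0, 2.2, 2.1, 1.9, 1.5, 1.0, 0.7),
    u_m_s = rep(2, 9),
    gsw_m_s = seq(0.005, 0.003, length.out = 9),
    ec_mm_h = rep(0.2, 9),
    stringsAsFactors = FALSE
  )
}
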