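test_that("error metrics follow their printed definitions", {
  x <- c(1, 2, 3)
  m0 <- error_metrics(x, x)
  expect_equal(unlist(m0), c(rmse = 0, mae = 0, rel_err_pct = 0))

  m <- error_metrics(c(1, 2), c(2, 3))
  expect_equal(m$rmse, 1)
  expect_equal(m$mae, 1)
  expect_equal(m$rel_err_pct, 200 / 3, tolerance = 1e-12)

  # the aggregate-bias percentage cancels opposite errors, MAE does not
  m2 <- error_metrics(c(1, 3), c(2, 2))
  expect_equal(m2$rmse, 1)
  expect_equal(m2$mae, 1)
  expect_equal(m2$rel_err_pct, 0)

  expect_error(error_metrics(c(1, 2), c(1, 2, 3)), "obs has 2.*est has 3")
  expect_error(error_metrics(c(0, 0), c(1, 1)), "undefined metric")
})

test_that("rmse dominates mae with equality only for equal absolute errors", {
  set.seed(402)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    obs <- abs(rnorm(n)) + 0.1
    est <- obs + rnorm(n, sd = 0.3)
    m <- error_metrics(obs, est)
    expect_gte(m$rmse, m$mae - 1e-12)
  }
  # all absolute errors equal -> rmse == mae
  m_eq <- error_metrics(c(1, 2, 3), c(2, 1, 4))
  expect_equal(m_eq$rmse, m_eq$mae)
})

test_that("pearson correlation handles the degenerate cases explicitly", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_error(pearson_r(x, rep(2, 5)), "constant")
  expect_error(pearson_r(x[1], 2), "at least 2")
})

test_that("OLS matches the normal-equations oracle and flags perfect fits", {
  obs <- c(1, 2, 3, 4)
  est <- c(1.1, 1.9, 3.2, 3.8)
  fit <- ols_with_intercept(obs, est)
  orc <- oracle_ols(obs, est)
  expect_equal(fit$intercept, unname(orc["intercept"]), tolerance = 1e-10)
  expect_equal(fit$slope, unname(orc["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept_p, unname(oracle_intercept_p(obs, est)),
               tolerance = 1e-10)
  expect_identical(fit$p_flag, "ok")

  exact <- ols_with_intercept(obs, 2 * obs + 3)
  expect_equal(exact$intercept, 3)
  expect_equal(exact$slope, 2)
  expect_true(is.na(exact$intercept_p))
  expect_identical(exact$p_flag, "undefined_perfect_fit")

  set.seed(403)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- 0.5 + 1.3 * x + rnorm(n, sd = 0.4)
    fit <- ols_with_intercept(x, y)
    orc <- oracle_ols(x, y)
    expect_equal(fit$intercept, unname(orc["intercept"]), tolerance = 1e-9)
    expect_equal(fit$slope, unname(orc["slope"]), tolerance = 1e-9)
    expect_equal(fit$intercept_p, unname(oracle_intercept_p(x, y)),
                 tolerance = 1e-9)
  }
  expect_error(ols_with_intercept(c(1, 2), c(1, 2)), "at least 3")
  expect_error(ols_with_intercept(rep(1, 4), 1:4), "constant")
})

test_that("regression through the origin matches sum(xy)/sum(x^2)", {
  expect_equal(regression_through_origin(c(1, 2, 3), 2 * c(1, 2, 3))$slope, 2)
  rto <- regression_through_origin(c(1, 2, 3), c(2, 3, 5))
  expect_equal(rto$slope, 23 / 14, tolerance = 1e-12)
  # a noiseless proportional series recovers its constant exactly
  obs <- seq(5e-4, 3e-3, length.out = 20)
  prop <- regression_through_origin(obs, 1.051 * obs)
  expect_equal(prop$slope, 1.051, tolerance = 1e-12)
  expect_equal(prop$r, 1)

  set.seed(404)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    x <- rnorm(n)
    y <- 1.2 * x + rnorm(n, sd = 0.2)
    expect_equal(regression_through_origin(x, y)$slope,
                 oracle_rto_slope(x, y), tolerance = 1e-10)
  }
  # the two r conventions agree on a proportional fit
  u <- regression_through_origin(obs, 1.051 * obs, r_method = "uncentered")
  expect_equal(u$r, 1, tolerance = 1e-12)
  expect_error(regression_through_origin(rep(0, 3), 1:3), "all zero")
})

test_that("Cohen's d uses the pooled sample SD and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  # two samples with means 2 and 1, each SD 1, equal n
  a <- c(1, 2, 3)
  b <- c(0, 1, 2)
  cd <- cohens_d(a, b)
  expect_equal(cd$d, 1)
  expect_equal(cd$s_p, 1)
  expect_equal(cohens_d(b, a)$d, -1)
  # invariant under a common rescaling of both samples
  expect_equal(cohens_d(3 * a, 3 * b)$d, cd$d)
  expect_error(cohens_d(rep(1, 3), rep(2, 3)), "pooled variance")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("U1 non-overlap follows Cohen's table with an exact-normal fallback", {
  expect_equal(u1_nonoverlap(0), 0)
  expect_equal(u1_nonoverlap(0.2), 14.7)
  expect_equal(round(u1_nonoverlap(0.217), 1), 15.8)
  expect_equal(round(u1_nonoverlap(0.217, mode = "exact_normal"), 1), 15.9)
  expect_equal(u1_nonoverlap(-0.3), u1_nonoverlap(0.3))  # sign ignored

  d <- seq(0, 2, by = 0.01)
  tab <- u1_nonoverlap(d)
  exact <- u1_nonoverlap(d, mode = "exact_normal")
  expect_true(all(diff(tab) >= 0))
  expect_true(all(diff(exact) >= 0))
  expect_lt(max(abs(tab[d <= 1] - exact[d <= 1])), 0.5)
  expect_warning(far <- u1_nonoverlap(2.5), "beyond Cohen's table")
  expect_equal(far, u1_nonoverlap(2.5, mode = "exact_normal"))
})

test_that("coefficient of variation is the sample SD over the mean", {
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  x <- rnorm(50, mean = 10, sd = 1)
  expect_equal(coefficient_of_variation(x), sd(x) / mean(x) * 100)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(3), "at least 2")
})

test_that("the full evaluation report composes all statistics coherently", {
  obs <- seq(5e-4, 3e-3, length.out = 12)
  rep0 <- evaluate_model(obs, obs)
  expect_equal(rep0$rmse, 0)
  expect_equal(rep0$pearson_r, 1)
  expect_equal(rep0$rto_slope, 1)
  expect_equal(rep0$cohens_d, 0)
  expect_identical(rep0$intercept_p_flag, "undefined_perfect_fit")

  set.seed(405)
  est <- obs * 1.05 + rnorm(12, sd = 5e-5)
  r <- evaluate_model(obs, est)
  expect_s3_class(r, "evaluation_report")
  expect_identical(r$n, 12L)
  num <- unlist(r[setdiff(names(r), c("intercept_p_flag", "n"))])
  expect_true(all(is.finite(num)))
  expect_gte(r$rmse, r$mae)
  expect_true(r$u1_pct >= 0 && r$u1_pct < 100)

  # flagged records are excluded pairwise
  ts <- as_clock_time("2021-07-08 08:00") + seq_along(obs) * 3600
  cs_obs <- conductance_series(ts, c(NA, obs[-1]), "observed",
                               c("vpd_nonpositive", rep("ok", 11)))
  cs_est <- conductance_series(ts, est, "estimated")
  r2 <- evaluate_model(cs_obs, cs_est)
  expect_identical(r2$n, 11L)

  expect_error(evaluate_model(obs, est[-1]), "obs has 12.*est has 11")

  # serialization round-trips
  kv <- report_to_kv(r)
  expect_true(all(grepl(" = ", kv, fixed = TRUE)))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_report_csv(r, path)
  back <- read.csv(path)
  expect_equal(back$rto_slope, r$rto_slope, tolerance = 1e-12)
  expect_equal(back$u1_pct, r$u1_pct, tolerance = 1e-12)
  expect_identical(nrow(back), 1L)
})
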