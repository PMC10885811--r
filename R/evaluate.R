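# Cohen's published percentage-of-non-overlap (U1) values, indexed by |d|.
# Linear interpolation between these anchors is the package's default U1
# convention; the exact-normal expression is available as an alternative.
.cohen_u1_table <- data.frame(
  d  = c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0,
         1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9, 2.0),
  u1 = c(0, 7.7, 14.7, 21.3, 27.4, 33.0, 38.2, 43.0, 47.4, 51.6, 55.4,
         58.9, 62.2, 65.3, 68.1, 70.7, 73.1, 75.4, 77.4, 79.4, 81.1)
)

#' Error metrics between observed and estimated series
#'
#' Computes the three agreement metrics used to validate the big-leaf
#' estimator against the Penman-Monteith reference:
#' \deqn{RMSE = \sqrt{\sum_i (est_i - obs_i)^2 / n}}
#' \deqn{MAE = \sum_i |est_i - obs_i| / n}
#' \deqn{|E| = 100 \left|\sum_i (est_i - obs_i)\right| / \sum_i obs_i}
#' Note that `|E|` is an aggregate signed-bias percentage: errors of opposite
#' sign cancel before the absolute value is taken. It is not a mean absolute
#' relative error, and it can be zero while MAE is large.
#'
#' @param obs,est numeric vectors of equal length.
#' @return A list with `rmse`, `mae` and `rel_err_pct`.
#' @examples
#' error_metrics(c(1, 2), c(2, 3))  # rmse 1, mae 1, |E| 66.67
#' error_metrics(c(1, 3), c(2, 2))  # opposite errors cancel: |E| 0
#' @export
error_metrics <- function(obs, est) {
  .check_finite(obs, "obs"); .check_finite(est, "est")
  if (length(obs) != length(est)) {
    stop(sprintf("length mismatch: obs has %d values, est has %d",
                 length(obs), length(est)), call. = FALSE)
  }
  if (length(obs) < 1) stop("need at least one pair", call. = FALSE)
  err <- est - obs
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  rel <- if (sum(obs) == 0) {
    stop("undefined metric: sum of observations is zero, |E| has no scale",
         call. = FALSE)
  } else {
    abs(sum(err)) / sum(obs) * 100
  }
  list(rmse = rmse, mae = mae, rel_err_pct = rel)
}

#' Pearson correlation between observed and estimated series
#'
#' Standard product-moment correlation, with explicit errors for the
#' degenerate inputs (constant series) on which it is undefined.
#'
#' @param obs,est numeric vectors of equal length, n >= 2, neither constant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(obs, est) {
  .check_finite(obs, "obs"); .check_finite(est, "est")
  if (length(obs) != length(est)) {
    stop(sprintf("length mismatch: obs has %d values, est has %d",
                 length(obs), length(est)), call. = FALSE)
  }
  if (length(obs) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (stats::sd(obs) == 0 || stats::sd(est) == 0) {
    stop("undefined correlation: constant series", call. = FALSE)
  }
  stats::cor(obs, est)
}

#' Ordinary least squares with an intercept hypothesis test
#'
#' Fits `est = b0 + b1 * obs + e` by least squares and tests
#' `H0: b0 = 0` with the two-sided t statistic `b0 / SE(b0)` on `n - 2`
#' degrees of freedom. A non-significant intercept justifies refitting
#' through the origin ([regression_through_origin()]).
#'
#' For an exact fit (zero residual variance) the standard error vanishes and
#' the p-value is reported as `NA` with `p_flag = "undefined_perfect_fit"`,
#' never as 0.
#'
#' @param obs,est numeric vectors of equal length, n >= 3; `obs` non-constant.
#' @return A list with `intercept` (b0), `slope` (b1), `intercept_p` and
#'   `p_flag` (`"ok"` or `"undefined_perfect_fit"`).
#' @export
ols_with_intercept <- function(obs, est) {
  .check_finite(obs, "obs"); .check_finite(est, "est")
  if (length(obs) != length(est)) {
    stop(sprintf("length mismatch: obs has %d values, est has %d",
                 length(obs), length(est)), call. = FALSE)
  }
  n <- length(obs)
  if (n < 3) stop("need at least 3 pairs for the intercept test", call. = FALSE)
  if (stats::sd(obs) == 0) {
    stop("'obs' is constant; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(est ~ obs)
  b <- stats::coef(fit)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  scale <- max(abs(est), 1e-300)
  if (sigma <= 1e-12 * scale) {
    return(list(intercept = unname(b[1]), slope = unname(b[2]),
                intercept_p = NA_real_, p_flag = "undefined_perfect_fit"))
  }
  p <- summary(fit)$coefficients["(Intercept)", "Pr(>|t|)"]
  list(intercept = unname(b[1]), slope = unname(b[2]),
       intercept_p = unname(p), p_flag = "ok")
}

#' Regression through the origin
#'
#' Least-squares fit of `est = slope * obs` with no intercept:
#' `slope = sum(obs * est) / sum(obs^2)`. The accompanying correlation is, by
#' default, the Pearson correlation between `est` and the fitted values
#' `slope * obs` (method `"pearson_fitted"`); method `"uncentered"` instead
#' reports the square root of the uncentered R-squared,
#' `sqrt(1 - RSS / sum(est^2))`.
#'
#' @param obs,est numeric vectors of equal length; `obs` not all zero.
#' @param r_method correlation convention, `"pearson_fitted"` (default) or
#'   `"uncentered"`.
#' @return A list with `slope` and `r`.
#' @examples
#' regression_through_origin(c(1, 2, 3), c(2, 3, 5))  # slope 23/14
#' @export
regression_through_origin <- function(obs, est,
                                      r_method = c("pearson_fitted",
                                                   "uncentered")) {
  r_method <- match.arg(r_method)
  .check_finite(obs, "obs"); .check_finite(est, "est")
  if (length(obs) != length(est)) {
    stop(sprintf("length mismatch: obs has %d values, est has %d",
                 length(obs), length(est)), call. = FALSE)
  }
  if (sum(obs^2) == 0) {
    stop("'obs' is all zero; slope through the origin undefined",
         call. = FALSE)
  }
  fit <- stats::lm(est ~ obs + 0)
  slope <- unname(stats::coef(fit)[1])
  fitted <- slope * obs
  r <- switch(r_method,
    pearson_fitted = {
      if (stats::sd(fitted) == 0 || stats::sd(est) == 0) {
        NA_real_
      } else {
        stats::cor(est, fitted)
      }
    },
    uncentered = {
      rss <- sum((est - fitted)^2)
      sqrt(max(0, 1 - rss / sum(est^2)))
    }
  )
  list(slope = slope, r = r)
}

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference between the observed and estimated samples,
#' \deqn{d = (\bar{obs} - \bar{est}) / s_p,\qquad
#'  s_p = \sqrt{\frac{(N_{obs}-1) s_{obs}^2 + (N_{est}-1) s_{est}^2}
#'              {N_{obs}+N_{est}-2}}}
#' with sample variances (N - 1 denominators). Antisymmetric under swapping
#' the samples; invariant under a common rescaling of both.
#'
#' @param obs,est numeric vectors, each with at least 2 values.
#' @return A list with `d` and `s_p`.
#' @export
cohens_d <- function(obs, est) {
  .check_finite(obs, "obs"); .check_finite(est, "est")
  n1 <- length(obs); n2 <- length(est)
  if (n1 < 2 || n2 < 2) {
    stop("need at least 2 values per sample", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * stats::var(obs) + (n2 - 1) * stats::var(est)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    stop("undefined effect size: pooled variance is zero", call. = FALSE)
  }
  sp <- sqrt(sp2)
  list(d = (mean(obs) - mean(est)) / sp, s_p = sp)
}

#' Percentage of distributional non-overlap (Cohen's U1)
#'
#' Converts an effect size to the percentage of the two distributions that
#' does not overlap, under the equal-variance normal model. Mode
#' `"table_interpolation"` (the default) interpolates linearly between
#' Cohen's published U1 values on `|d|`; mode `"exact_normal"` evaluates the
#' closed form \eqn{U_1 = (2\Phi(|d|/2) - 1)/\Phi(|d|/2)}. The two agree to a
#' few tenths of a percentage point for small effects but round differently
#' (e.g. at d = 0.217 the table gives 15.8, the closed form 15.9). Beyond the
#' table range (|d| > 2) the table mode falls back to the closed form with a
#' warning.
#'
#' @param d effect size (Cohen's d); the sign is ignored.
#' @param mode `"table_interpolation"` or `"exact_normal"`.
#' @return Non-overlap percentage in \[0, 100).
#' @examples
#' u1_nonoverlap(0.217)                        # 15.8 (table convention)
#' u1_nonoverlap(0.217, mode = "exact_normal") # 15.9
#' @export
u1_nonoverlap <- function(d, mode = c("table_interpolation", "exact_normal")) {
  mode <- match.arg(mode)
  .check_finite(d, "d")
  ad <- abs(d)
  exact <- function(a) {
    phi <- stats::pnorm(a / 2)
    100 * (2 * phi - 1) / phi
  }
  if (mode == "exact_normal") return(exact(ad))
  out <- numeric(length(ad))
  beyond <- ad > max(.cohen_u1_table$d)
  if (any(beyond)) {
    warning("|d| beyond Cohen's table range; using exact-normal U1",
            call. = FALSE)
    out[beyond] <- exact(ad[beyond])
  }
  if (any(!beyond)) {
    out[!beyond] <- stats::approx(.cohen_u1_table$d, .cohen_u1_table$u1,
                                  xout = ad[!beyond])$y
  }
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation (N - 1 denominator) over the mean, as a
#' percentage.
#'
#' @param x numeric vector, n >= 2, non-zero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(1, 2, 3))  # 50
#' @export
coefficient_of_variation <- function(x) {
  .check_finite(x, "x")
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(x)
  if (m == 0) {
    stop("undefined metric: zero mean, CV has no scale", call. = FALSE)
  }
  stats::sd(x) / m * 100
}

#' Full model-agreement evaluation
#'
#' Composes every agreement statistic into one report: error metrics
#' ([error_metrics()]), Pearson correlation, OLS with the intercept test
#' ([ols_with_intercept()]), regression through the origin
#' ([regression_through_origin()]), Cohen's d with pooled SD
#' ([cohens_d()]), U1 non-overlap ([u1_nonoverlap()]) and the coefficients
#' of variation of both series. Records flagged invalid in either series
#' (non-`"ok"` `qc_flag` or `NA`) are excluded pairwise before computing.
#'
#' @param obs,est [conductance_series()] objects (or plain numeric vectors)
#'   of equal length, aligned record-wise.
#' @param u1_mode U1 convention, passed to [u1_nonoverlap()].
#' @param rto_r_method correlation convention for the origin regression,
#'   passed to [regression_through_origin()].
#' @return An object of class `evaluation_report`: a named list with fields
#'   `n`, `rmse`, `mae`, `rel_err_pct`, `pearson_r`, `ols_intercept`,
#'   `ols_slope`, `intercept_p`, `intercept_p_flag`, `rto_slope`, `rto_r`,
#'   `cohens_d`, `pooled_sd`, `u1_pct`, `cv_obs`, `cv_est`.
#' @examples
#' obs <- c(1, 2, 3, 4, 5) * 1e-3
#' est <- obs * 1.05 + c(1, -1, 2, -2, 0) * 1e-5
#' evaluate_model(obs, est)
#' @export
evaluate_model <- function(obs, est,
                           u1_mode = c("table_interpolation", "exact_normal"),
                           rto_r_method = c("pearson_fitted", "uncentered")) {
  u1_mode <- match.arg(u1_mode)
  rto_r_method <- match.arg(rto_r_method)
  extract <- function(x) {
    if (inherits(x, "conductance_series")) {
      v <- x$gc_m_s
      v[x$qc_flag != "ok"] <- NA_real_
      v
    } else {
      as.numeric(x)
    }
  }
  vo <- extract(obs); ve <- extract(est)
  if (length(vo) != length(ve)) {
    stop(sprintf("length mismatch: obs has %d values, est has %d",
                 length(vo), length(ve)), call. = FALSE)
  }
  keep <- is.finite(vo) & is.finite(ve)
  vo <- vo[keep]; ve <- ve[keep]
  n <- length(vo)
  if (n < 3) {
    stop("need at least 3 valid aligned pairs to evaluate", call. = FALSE)
  }
  em <- error_metrics(vo, ve)
  ols <- ols_with_intercept(vo, ve)
  rto <- regression_through_origin(vo, ve, r_method = rto_r_method)
  cd <- cohens_d(vo, ve)
  structure(list(
    n = n,
    rmse = em$rmse, mae = em$mae, rel_err_pct = em$rel_err_pct,
    pearson_r = pearson_r(vo, ve),
    ols_intercept = ols$intercept, ols_slope = ols$slope,
    intercept_p = ols$intercept_p, intercept_p_flag = ols$p_flag,
    rto_slope = rto$slope, rto_r = rto$r,
    cohens_d = cd$d, pooled_sd = cd$s_p,
    u1_pct = u1_nonoverlap(cd$d, mode = u1_mode),
    cv_obs = coefficient_of_variation(vo),
    cv_est = coefficient_of_variation(ve)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Model agreement report (n =", x$n, "pairs)\n")
  cat(sprintf("  RMSE %0.4g   MAE %0.4g   |E| %0.3g %%\n",
              x$rmse, x$mae, x$rel_err_pct))
  cat(sprintf("  Pearson r %0.4f\n", x$pearson_r))
  pv <- if (is.na(x$intercept_p)) x$intercept_p_flag else
    sprintf("%0.4g", x$intercept_p)
  cat(sprintf("  OLS: est = %0.4g + %0.4f obs   (H0 b0=0: p = %s)\n",
              x$ols_intercept, x$ols_slope, pv))
  cat(sprintf("  Through origin: slope %0.4f   r %0.4f\n",
              x$rto_slope, x$rto_r))
  cat(sprintf("  Cohen's d %0.4f (pooled SD %0.4g)   U1 %0.1f %%\n",
              x$cohens_d, x$pooled_sd, x$u1_pct))
  cat(sprintf("  CV obs %0.2f %%   CV est %0.2f %%\n", x$cv_obs, x$cv_est))
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(x[names(x) != "intercept_p_flag"],
             intercept_p_flag = x$intercept_p_flag,
             stringsAsFactors = FALSE)
}

#' Serialize an evaluation report
#'
#' `report_to_kv()` renders the report as flat `key = value` text lines;
#' `write_report_csv()` writes it as a single-row CSV.
#'
#' @param report an `evaluation_report`.
#' @param path output file path (for `write_report_csv`).
#' @return `report_to_kv`: a character vector of lines.
#'   `write_report_csv`: the path, invisibly.
#' @export
report_to_kv <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  vapply(names(report), function(nm) {
    v <- report[[nm]]
    val <- if (is.numeric(v)) format(v, digits = 12) else as.character(v)
    paste0(nm, " = ", val)
  }, character(1))
}

#' @rdname report_to_kv
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
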