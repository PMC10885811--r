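#' Site and canopy parameters
#'
#' Describes the vineyard site: elevation, atmospheric pressure (derived from
#' elevation unless supplied), wind/humidity sensor height, canopy height and
#' leaf area index. The defaults are the study configuration: a 220 m
#' elevation site, sensors at 3 m, a 1.7 m trained canopy, and LAI
#' 1.96 m2 m-2.
#'
#' The sensor must sit above the roughness sublayer: with zero-plane
#' displacement \eqn{d = 2h/3} and momentum roughness length
#' \eqn{z_{om} = 0.123 h}, `z_m > d + z_om` is required.
#'
#' @param elevation site elevation above sea level, m.
#' @param z_m height of wind speed and humidity measurements, m.
#' @param h mean canopy height, m.
#' @param lai leaf area index, m2 m-2.
#' @param pressure atmospheric pressure, kPa; defaults to
#'   [pressure_from_elevation()] at `elevation`.
#'
#' @return An object of class `site_params` (a named list) including the
#'   derived roughness parameters `d_disp`, `z_om`, `z_ov`.
#' @examples
#' site_params()
#' @export
site_params <- function(elevation = 220, z_m = 3, h = 1.7, lai = 1.96,
                        pressure = pressure_from_elevation(elevation)) {
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0) {
    stop("'h' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(lai) || length(lai) != 1 || !is.finite(lai) || lai <= 0) {
    stop("'lai' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(pressure) || length(pressure) != 1 || pressure <= 0) {
    stop("'pressure' must be a single positive number", call. = FALSE)
  }
  d_disp <- 2 * h / 3       # zero-plane displacement
  z_om <- 0.123 * h         # momentum roughness length
  z_ov <- 0.1 * z_om        # water vapor roughness length
  if (!is.numeric(z_m) || length(z_m) != 1 || z_m <= d_disp + z_om) {
    stop(sprintf(
      "sensor below roughness sublayer: z_m = %g must exceed d + z_om = %g m",
      z_m, d_disp + z_om), call. = FALSE)
  }
  structure(
    list(elevation = elevation, pressure = pressure, z_m = z_m, h = h,
         lai = lai, d_disp = d_disp, z_om = z_om, z_ov = z_ov),
    class = "site_params"
  )
}

#' @export
print.site_params <- function(x, ...) {
  cat("Site parameters:\n")
  cat(sprintf("  elevation  %g m   pressure %0.3f kPa\n", x$elevation, x$pressure))
  cat(sprintf("  z_m %g m   canopy h %g m   LAI %g m2/m2\n", x$z_m, x$h, x$lai))
  cat(sprintf("  d %0.4f m   z_om %0.4f m   z_ov %0.5f m\n",
              x$d_disp, x$z_om, x$z_ov))
  invisible(x)
}

#' Aerodynamic conductance from the logarithmic wind profile
#'
#' \deqn{g_a = \frac{k^2 U}{\ln[(z_m - d)/z_{om}]\,\ln[(z_m - d)/z_{ov}]}}
#' with \eqn{d = 2h/3}, \eqn{z_{om} = 0.123h}, \eqn{z_{ov} = 0.1 z_{om}}.
#' Neutral stability is assumed (no stability corrections). Linear in wind
#' speed.
#'
#' @param u wind speed at `site$z_m`, m s-1 (non-negative; vectorized).
#' @param site a [site_params()] object.
#' @param constants a [physical_constants()] bundle.
#' @return Aerodynamic conductance, m s-1.
#' @examples
#' aerodynamic_conductance(2, site_params())  # ~0.0342 m s-1
#' @export
aerodynamic_conductance <- function(u, site = site_params(),
                                    constants = physical_constants()) {
  .check_finite(u, "u")
  if (any(u < 0)) stop("'u' must be non-negative", call. = FALSE)
  zd <- site$z_m - site$d_disp
  denom <- log(zd / site$z_om) * log(zd / site$z_ov)
  constants$k_vonkarman^2 * u / denom
}

#' Big-leaf canopy conductance estimator
#'
#' The biophysical big-leaf model
#' \deqn{g_{c\,est} = LAI \left(\frac{g_{sw} R_n}{VPD}\right)^{0.5}}
#' evaluated with its native unit recipe: stomatal conductance in m s-1, net
#' radiation in MJ m-2 h-1 and VPD in Pa. No hidden SI conversion is applied
#' — this mixed-unit recipe is part of the model definition and is what
#' produces canopy conductances on the observed m s-1 scale (an SI-converted
#' variant would differ by a factor sqrt(1e6/3600) and is deliberately not
#' provided).
#'
#' @param lai leaf area index, m2 m-2 (> 0).
#' @param g_sw canopy-representative stomatal conductance, m s-1 (>= 0).
#' @param rn net radiation above the canopy, MJ m-2 h-1 (>= 0).
#' @param vpd_pa air vapor pressure deficit, Pa (> 0).
#' @return Estimated canopy conductance, m s-1.
#' @examples
#' estimate_canopy_conductance(1.96, 0.005, 2, 2500)  # 0.00392 m s-1
#' @export
estimate_canopy_conductance <- function(lai, g_sw, rn, vpd_pa) {
  .check_finite(lai, "lai"); .check_finite(g_sw, "g_sw")
  .check_finite(rn, "rn");   .check_finite(vpd_pa, "vpd_pa")
  if (any(lai <= 0)) stop("'lai' must be positive", call. = FALSE)
  if (any(g_sw < 0)) stop("'g_sw' must be non-negative", call. = FALSE)
  if (any(rn < 0)) stop("'rn' must be non-negative", call. = FALSE)
  if (any(vpd_pa <= 0)) stop("'vpd_pa' must be positive", call. = FALSE)
  lai * sqrt(g_sw * rn / vpd_pa)
}

# Shared Penman-Monteith intermediates at (t_air, site pressure).
.pm_terms <- function(t_air, site, constants) {
  list(
    delta = slope_vapor_pressure_curve(t_air),
    gamma = psychrometric_constant(site$pressure, constants),
    rho = air_density(t_air, site$pressure, constants)
  )
}

#' Reference canopy conductance by Penman-Monteith inversion
#'
#' Inverts the Penman-Monteith combination equation for bulk surface
#' conductance, the reference ("observed") canopy conductance:
#' \deqn{g_{c\,obs} = \frac{\gamma \lambda E_c g_a}
#'   {\Delta R_n + k_t \rho C_p\, VPD\, g_a - \lambda (\Delta + \gamma) E_c}}
#' Soil heat flux is omitted (negligible over the hourly daytime records this
#' is intended for). VPD enters in kPa here, for dimensional consistency
#' with \eqn{\Delta} and \eqn{\gamma} in kPa degC-1.
#'
#' The denominator vanishes when transpiration reaches the energy/advection
#' bound for the given meteorology; beyond it the inversion is undefined and
#' an error ("non-invertible regime") is raised.
#'
#' @param e_c canopy transpiration, mm h-1 (>= 0).
#' @param rn net radiation, MJ m-2 h-1.
#' @param vpd_kpa vapor pressure deficit, kPa.
#' @param t_air air temperature, degC.
#' @param site a [site_params()] object (supplies atmospheric pressure).
#' @param g_a aerodynamic conductance, m s-1 (> 0).
#' @param constants a [physical_constants()] bundle.
#' @return Observed canopy conductance, m s-1.
#' @seealso [forward_penman_monteith()] for the exact algebraic inverse.
#' @examples
#' site <- site_params()
#' ga <- aerodynamic_conductance(2, site)
#' ec <- forward_penman_monteith(0.002, 2, 2.546, 30, site, ga)
#' invert_penman_monteith(ec, 2, 2.546, 30, site, ga)  # recovers 0.002
#' @export
invert_penman_monteith <- function(e_c, rn, vpd_kpa, t_air,
                                   site = site_params(), g_a,
                                   constants = physical_constants()) {
  .check_finite(e_c, "e_c"); .check_finite(rn, "rn")
  .check_finite(vpd_kpa, "vpd_kpa"); .check_finite(g_a, "g_a")
  if (any(e_c < 0)) stop("'e_c' must be non-negative", call. = FALSE)
  if (any(g_a <= 0)) stop("'g_a' must be positive", call. = FALSE)
  tm <- .pm_terms(t_air, site, constants)
  lam <- constants$lambda_vap
  denom <- tm$delta * rn + constants$kt * tm$rho * constants$cp * vpd_kpa * g_a -
    lam * (tm$delta + tm$gamma) * e_c
  if (any(denom <= 0)) {
    stop("non-invertible regime: transpiration exceeds the energy/advection ",
         "bound for these inputs (denominator <= 0)", call. = FALSE)
  }
  tm$gamma * lam * e_c * g_a / denom
}

#' Forward Penman-Monteith canopy transpiration
#'
#' The combination equation solved for transpiration at a known canopy
#' conductance — the exact algebraic inverse of [invert_penman_monteith()]:
#' \deqn{E_c = \frac{\Delta R_n + k_t \rho C_p\, VPD\, g_a}
#'   {\lambda [\Delta + \gamma (1 + g_a/g_c)]}}
#' Used to synthesize transpiration consistent with a known conductance and
#' for round-trip testing; strictly increasing in `g_c` at fixed meteorology.
#'
#' @param g_c canopy conductance, m s-1 (> 0).
#' @inheritParams invert_penman_monteith
#' @return Canopy transpiration, mm h-1.
#' @examples
#' forward_penman_monteith(0.002, 2, 2.546, 30, site_params(),
#'                         g_a = 0.0342)  # ~0.24 mm h-1
#' @export
forward_penman_monteith <- function(g_c, rn, vpd_kpa, t_air,
                                    site = site_params(), g_a,
                                    constants = physical_constants()) {
  .check_finite(g_c, "g_c"); .check_finite(rn, "rn")
  .check_finite(vpd_kpa, "vpd_kpa"); .check_finite(g_a, "g_a")
  if (any(g_c <= 0)) stop("'g_c' must be positive", call. = FALSE)
  if (any(g_a <= 0)) stop("'g_a' must be positive", call. = FALSE)
  tm <- .pm_terms(t_air, site, constants)
  num <- tm$delta * rn + constants$kt * tm$rho * constants$cp * vpd_kpa * g_a
  den <- constants$lambda_vap * (tm$delta + tm$gamma * (1 + g_a / g_c))
  num / den
}

#' Construct a conductance series
#'
#' A timestamped series of canopy conductance values with a provenance tag
#' and per-record QC flags. Invalid records carry `NA` plus a reason code in
#' `qc_flag` rather than being dropped.
#'
#' @param timestamp POSIXct (or coercible) timestamps.
#' @param gc_m_s conductance values, m s-1 (`NA` for flagged records).
#' @param provenance one of `"estimated"`, `"observed"`, `"true_synthetic"`.
#' @param qc_flag character reason codes; `"ok"` for valid records.
#' @return A `conductance_series` data.frame.
#' @export
conductance_series <- function(timestamp, gc_m_s,
                               provenance = c("estimated", "observed",
                                              "true_synthetic"),
                               qc_flag = "ok") {
  provenance <- match.arg(provenance)
  timestamp <- as_clock_time(timestamp)
  df <- data.frame(timestamp = timestamp, gc_m_s = as.numeric(gc_m_s),
                   provenance = provenance,
                   qc_flag = rep_len(as.character(qc_flag), length(gc_m_s)),
                   stringsAsFactors = FALSE)
  bad <- !is.na(df$gc_m_s) & df$gc_m_s <= 0
  if (any(bad)) {
    stop("conductance values must be positive for valid records; ",
         "flag invalid records as NA with a qc_flag reason", call. = FALSE)
  }
  class(df) <- c("conductance_series", "data.frame")
  df
}

#' @export
print.conductance_series <- function(x, ...) {
  ok <- sum(x$qc_flag == "ok")
  cat(sprintf("Conductance series (%s): %d records, %d valid\n",
              x$provenance[1], nrow(x), ok))
  if (ok > 0) {
    v <- x$gc_m_s[x$qc_flag == "ok"]
    cat(sprintf("  range %0.5g - %0.5g m s-1, mean %0.5g\n",
                min(v), max(v), mean(v)))
  }
  NextMethod()
}

#' Record-wise estimated and observed conductance from an aligned table
#'
#' Applies the big-leaf estimator and the Penman-Monteith inversion to every
#' row of an analysis-ready table (as produced by [align_records()]):
#' computes VPD from temperature and humidity, aerodynamic conductance from
#' wind speed, the estimated conductance from `(LAI, g_sw, R_n, VPD)` and the
#' observed conductance from `(E_c, R_n, VPD, T, g_a)`. Rows violating any
#' operation's preconditions (non-positive VPD, negative flux, non-invertible
#' regime) are flagged `NA` with a reason code instead of aborting the batch.
#'
#' @param aligned data.frame with columns `timestamp`, `t_air_c`, `rh_pct`,
#'   `rn_mj_m2_h`, `u_m_s`, `gsw_m_s`, `ec_mm_h`.
#' @param site a [site_params()] object.
#' @param constants a [physical_constants()] bundle.
#' @return A list with `estimated` and `observed` [conductance_series()] of
#'   equal length (one row per input row).
#' @export
conductance_pipeline <- function(aligned, site = site_params(),
                                 constants = physical_constants()) {
  need <- c("timestamp", "t_air_c", "rh_pct", "rn_mj_m2_h", "u_m_s",
            "gsw_m_s", "ec_mm_h")
  miss <- setdiff(need, names(aligned))
  if (length(miss) > 0) {
    stop("aligned table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(aligned) == 0) {
    stop("empty aligned input: nothing to compute", call. = FALSE)
  }
  n <- nrow(aligned)
  est <- rep(NA_real_, n)
  obs <- rep(NA_real_, n)
  flag_est <- rep("ok", n)
  flag_obs <- rep("ok", n)

  vpd_kpa <- suppressWarnings(
    vapor_pressure_deficit(aligned$t_air_c, aligned$rh_pct))
  g_a <- aerodynamic_conductance(aligned$u_m_s, site, constants)

  for (i in seq_len(n)) {
    if (!is.finite(vpd_kpa[i]) || vpd_kpa[i] <= 0) {
      flag_est[i] <- flag_obs[i] <- "vpd_nonpositive"
      next
    }
    est[i] <- tryCatch(
      estimate_canopy_conductance(site$lai, aligned$gsw_m_s[i],
                                  aligned$rn_mj_m2_h[i], 1000 * vpd_kpa[i]),
      error = function(e) NA_real_)
    if (is.na(est[i])) flag_est[i] <- "estimator_precondition"
    obs[i] <- tryCatch(
      invert_penman_monteith(aligned$ec_mm_h[i], aligned$rn_mj_m2_h[i],
                             vpd_kpa[i], aligned$t_air_c[i], site, g_a[i],
                             constants),
      error = function(e) NA_real_)
    if (is.na(obs[i])) {
      flag_obs[i] <- if (!is.finite(aligned$ec_mm_h[i]) ||
                           aligned$ec_mm_h[i] < 0) {
        "flux_invalid"
      } else "non_invertible_regime"
    } else if (obs[i] <= 0) {
      # e_c == 0 inverts to exactly zero conductance; flag, don't keep
      obs[i] <- NA_real_
      flag_obs[i] <- "zero_flux"
    }
    if (!is.na(est[i]) && est[i] <= 0) {
      est[i] <- NA_real_
      flag_est[i] <- "zero_gsw"
    }
  }
  list(
    estimated = conductance_series(aligned$timestamp, est, "estimated",
                                   flag_est),
    observed = conductance_series(aligned$timestamp, obs, "observed",
                                  flag_obs)
  )
}
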