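# Run code under a seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic Mediterranean-summer scenario parameters
#'
#' Defines the diurnal shapes and stochastic settings of the synthetic
#' vineyard generator. The defaults emulate a hot, dry Mediterranean summer
#' day: a half-sine net-radiation course peaking at 13:00 local (2.2
#' MJ m-2 h-1 at the peak), air temperature rising from 18 degC at dawn to a
#' 36 degC peak two hours after solar noon, relative humidity mirroring
#' temperature between 70 % and 25 %, light wind (lognormal, mean 2 m s-1),
#' and a light-saturating, VPD-limited stomatal conductance with a
#' 0.25 mol m-2 s-1 ceiling. Sampling covers 09:00-19:00 hourly.
#'
#' @param window_start,window_end clock times `"HH:MM"` of the sampled window.
#' @param rn_peak peak net radiation, MJ m-2 h-1.
#' @param t_dawn,t_peak dawn and peak air temperature, degC.
#' @param rh_dawn,rh_min dawn and minimum relative humidity, percent
#'   (`rh_min < rh_dawn <= 100`).
#' @param u_mean mean wind speed, m s-1.
#' @param gsw_max maximal stomatal conductance, mol m-2 s-1.
#' @param k_r radiation half-saturation constant, MJ m-2 h-1.
#' @param d0 VPD sensitivity parameter, kPa.
#' @param noise_sd_rel relative SD of multiplicative lognormal noise applied
#'   to transpiration (0 = noiseless).
#' @param model_mismatch_rel relative perturbation between the true canopy
#'   conductance and the big-leaf estimate (0 = the estimator is exact).
#' @param seed integer RNG seed.
#' @return An object of class `scenario_params`.
#' @export
scenario_params <- function(window_start = "09:00", window_end = "19:00",
                            rn_peak = 2.2, t_dawn = 18, t_peak = 36,
                            rh_dawn = 70, rh_min = 25, u_mean = 2.0,
                            gsw_max = 0.25, k_r = 0.5, d0 = 1.5,
                            noise_sd_rel = 0, model_mismatch_rel = 0,
                            seed = 1L) {
  pos <- c(rn_peak = rn_peak, t_dawn = t_dawn, t_peak = t_peak,
           rh_dawn = rh_dawn, rh_min = rh_min, u_mean = u_mean,
           gsw_max = gsw_max, k_r = k_r, d0 = d0)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all physical scenario parameters must be positive", call. = FALSE)
  }
  if (rh_min >= rh_dawn || rh_dawn > 100) {
    stop("'rh_min' must be below 'rh_dawn', and 'rh_dawn' <= 100",
         call. = FALSE)
  }
  if (noise_sd_rel < 0 || !is.finite(noise_sd_rel)) {
    stop("'noise_sd_rel' must be non-negative", call. = FALSE)
  }
  ws <- parse_clock(window_start)
  we <- parse_clock(window_end)
  if (ws >= we) stop("'window_start' must precede 'window_end'", call. = FALSE)
  structure(list(
    window_start = window_start, window_end = window_end, ws_h = ws,
    we_h = we, rn_peak = rn_peak, t_dawn = t_dawn, t_peak = t_peak,
    rh_dawn = rh_dawn, rh_min = rh_min, u_mean = u_mean, gsw_max = gsw_max,
    k_r = k_r, d0 = d0, noise_sd_rel = noise_sd_rel,
    model_mismatch_rel = model_mismatch_rel, seed = as.integer(seed),
    # fixed day geometry: sun above horizon 06:30-19:30, so R_n peaks at
    # 13:00 and T_air (2 h lag) at 15:00
    sunrise_h = 6.5, sunset_h = 19.5, t_lag_h = 2, u_sdlog = 0.3
  ), class = "scenario_params")
}

# Deterministic diurnal curves at decimal hour h (vectorized).
.rn_curve <- function(h, p) {
  frac <- (h - p$sunrise_h) / (p$sunset_h - p$sunrise_h)
  pmax(0, p$rn_peak * sin(pi * pmin(pmax(frac, 0), 1)))
}

.t_curve <- function(h, p) {
  t_peak_h <- (p$sunrise_h + p$sunset_h) / 2 + p$t_lag_h
  half <- t_peak_h - p$sunrise_h
  p$t_dawn + (p$t_peak - p$t_dawn) *
    sin(pi * pmin(pmax(h - p$sunrise_h, 0), 2 * half) / (2 * half))
}

.rh_curve <- function(h, p) {
  t <- .t_curve(h, p)
  p$rh_dawn - (p$rh_dawn - p$rh_min) * (t - p$t_dawn) / (p$t_peak - p$t_dawn)
}

# One day of meteo drawn from the current RNG stream (no reseeding).
.diurnal_meteo_day <- function(params, date) {
  hours <- seq(floor(params$ws_h), floor(params$we_h))
  ts <- as_clock_time(sprintf("%s %02d:00:00", date, hours))
  n <- length(hours)
  sdlog <- params$u_sdlog
  u <- stats::rlnorm(n, meanlog = log(params$u_mean) - sdlog^2 / 2,
                     sdlog = sdlog)
  data.frame(
    timestamp = ts,
    t_air_c = .t_curve(hours, params),
    rh_pct = .rh_curve(hours, params),
    rn_mj_m2_h = .rn_curve(hours, params),
    u_m_s = u,
    stringsAsFactors = FALSE
  )
}

#' Generate one synthetic diurnal meteorological day
#'
#' Hourly weather records over the scenario window: a half-sine net-radiation
#' course peaking at solar noon, a sinusoidal air-temperature course lagging
#' radiation by two hours, relative humidity mirroring temperature between
#' its dawn and minimum values, and seeded lognormal wind. Deterministic
#' given `params$seed`.
#'
#' @param params a [scenario_params()] object.
#' @param date calendar date of the simulated day, `"YYYY-MM-DD"`.
#' @return data.frame with columns `timestamp`, `t_air_c`, `rh_pct`,
#'   `rn_mj_m2_h`, `u_m_s` (one row per hour of the window).
#' @examples
#' head(diurnal_meteo(scenario_params(seed = 7)))
#' @export
diurnal_meteo <- function(params = scenario_params(), date = "2021-07-08") {
  with_seed(params$seed, .diurnal_meteo_day(params, date))
}

#' Stomatal conductance response to light and vapor pressure deficit
#'
#' Multiplicative two-factor stomatal model: a saturating (Michaelis-Menten)
#' response to net radiation times a hyperbolic decline with VPD,
#' \deqn{g_{sw} = g_{sw,max} \frac{R_n}{R_n + k_r}
#'       \frac{1}{1 + VPD/D_0}}
#' bounded by `gsw_max`. This reproduces the characteristic vineyard diurnal
#' course: conductance peaks mid-morning once light saturates, then declines
#' through the afternoon as VPD rises.
#'
#' @param rn net radiation, MJ m-2 h-1 (>= 0).
#' @param vpd_kpa vapor pressure deficit, kPa (>= 0).
#' @param params a [scenario_params()] object (supplies `gsw_max`, `k_r`,
#'   `d0`).
#' @return Stomatal conductance, mol m-2 s-1.
#' @examples
#' jarvis_gsw(2, 2.5)
#' @export
jarvis_gsw <- function(rn, vpd_kpa, params = scenario_params()) {
  .check_finite(rn, "rn"); .check_finite(vpd_kpa, "vpd_kpa")
  if (any(rn < 0) || any(vpd_kpa < 0)) {
    stop("'rn' and 'vpd_kpa' must be non-negative", call. = FALSE)
  }
  params$gsw_max * (rn / (rn + params$k_r)) * (1 / (1 + vpd_kpa / params$d0))
}

#' Generate a full synthetic measurement campaign
#'
#' Builds an `n_days` campaign of hourly vineyard data with a known
#' ground-truth canopy conductance. For each hour the generator: (1) draws
#' the diurnal meteorology; (2) computes the stomatal conductance from light
#' and VPD ([jarvis_gsw()]) and splits it into east/west leaf samples with a
#' fixed +/-10 % sun-exposure asymmetry (east boosted before solar noon, west
#' after — the mean of the two sides is exact); (3) sets the true canopy
#' conductance to `(1 + model_mismatch_rel)` times the big-leaf estimate; (4)
#' produces canopy transpiration from the true conductance via the forward
#' Penman-Monteith relation, with optional multiplicative lognormal noise.
#' Fully deterministic given `params$seed` (one RNG stream for the whole
#' campaign).
#'
#' With `noise_sd_rel = 0` and `model_mismatch_rel = 0` the full analysis
#' pipeline recovers the truth exactly: inverting Penman-Monteith on the
#' generated transpiration returns the true conductance, and the big-leaf
#' estimate equals it.
#'
#' @param params a [scenario_params()] object.
#' @param n_days number of consecutive campaign days (>= 1).
#' @param site a [site_params()] object.
#' @param start_date first campaign day, `"YYYY-MM-DD"`.
#' @param constants a [physical_constants()] bundle.
#' @return An object of class `campaign`: a list of data.frames `meteo`
#'   (`timestamp, t_air_c, rh_pct, rn_mj_m2_h, u_m_s`), `leaf`
#'   (`timestamp, side, gsw_value, gsw_unit`; units mol m-2 s-1), `flux`
#'   (`timestamp, ec_mm_h`) and `truth` (`timestamp, gc_true_m_s`), plus the
#'   generating `params` and `site`.
#' @examples
#' camp <- generate_campaign(scenario_params(seed = 42), n_days = 1)
#' str(camp$truth)
#' @export
generate_campaign <- function(params = scenario_params(), n_days = 5,
                              site = site_params(),
                              start_date = "2021-07-01",
                              constants = physical_constants()) {
  if (!is.numeric(n_days) || n_days < 1) {
    stop("'n_days' must be at least 1", call. = FALSE)
  }
  solar_noon <- (params$sunrise_h + params$sunset_h) / 2
  dates <- format(as.Date(start_date) + seq_len(n_days) - 1)
  with_seed(params$seed, {
    days <- lapply(dates, function(d) .diurnal_meteo_day(params, d))
    meteo <- do.call(rbind, days)
    n <- nrow(meteo)

    vpd_kpa <- vapor_pressure_deficit(meteo$t_air_c, meteo$rh_pct)
    gsw_mol <- jarvis_gsw(meteo$rn_mj_m2_h, vpd_kpa, params)
    rho_mol <- molar_density_air(meteo$t_air_c, site$pressure, constants)
    gsw_ms <- gsw_mol / rho_mol

    gc_true <- (1 + params$model_mismatch_rel) *
      estimate_canopy_conductance(site$lai, gsw_ms, meteo$rn_mj_m2_h,
                                  1000 * vpd_kpa)

    g_a <- aerodynamic_conductance(meteo$u_m_s, site, constants)
    e_c <- forward_penman_monteith(gc_true, meteo$rn_mj_m2_h, vpd_kpa,
                                   meteo$t_air_c, site, g_a, constants)
    if (params$noise_sd_rel > 0) {
      sdlog <- sqrt(log(1 + params$noise_sd_rel^2))
      e_c <- e_c * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }

    morning <- clock_hour(meteo$timestamp) < solar_noon
    boost <- ifelse(morning, 1.1, 0.9)
    leaf <- data.frame(
      timestamp = rep(meteo$timestamp, each = 2),
      side = rep(c("east", "west"), times = n),
      gsw_value = as.vector(rbind(gsw_mol * boost, gsw_mol * (2 - boost))),
      gsw_unit = "mol_m2_s",
      stringsAsFactors = FALSE
    )

    structure(list(
      meteo = meteo,
      leaf = leaf,
      flux = data.frame(timestamp = meteo$timestamp, ec_mm_h = e_c,
                        stringsAsFactors = FALSE),
      truth = data.frame(timestamp = meteo$timestamp, gc_true_m_s = gc_true,
                         stringsAsFactors = FALSE),
      params = params, site = site
    ), class = "campaign")
  })
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("Synthetic campaign: %d meteo records, %d leaf samples, seed %d\n",
              nrow(x$meteo), nrow(x$leaf), x$params$seed))
  cat(sprintf("  true g_c range %0.5g - %0.5g m s-1\n",
              min(x$truth$gc_true_m_s), max(x$truth$gc_true_m_s)))
  invisible(x)
}
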