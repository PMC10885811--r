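#' Data-conditioning configuration
#'
#' Filtering rules applied before conductance analysis: a daylight clock
#' window, a minimum net-radiation threshold, and the interquartile-range
#' outlier cut-off. Defaults are the field protocol: keep records between
#' 10:00 and 18:00 (inclusive) with net radiation of at least
#' 0.60 MJ m-2 h-1, and screen with 1.5 x IQR fences.
#'
#' @param window_start,window_end clock times `"HH:MM"` bounding the retained
#'   daylight window (inclusive).
#' @param rn_min minimum net radiation, MJ m-2 h-1.
#' @param iqr_k IQR fence multiplier, dimensionless.
#' @return An object of class `filter_config`.
#' @examples
#' filter_config()
#' @export
filter_config <- function(window_start = "10:00", window_end = "18:00",
                          rn_min = 0.60, iqr_k = 1.5) {
  ws <- parse_clock(window_start)
  we <- parse_clock(window_end)
  if (ws >= we) stop("'window_start' must precede 'window_end'", call. = FALSE)
  if (!is.numeric(rn_min) || rn_min < 0) {
    stop("'rn_min' must be non-negative", call. = FALSE)
  }
  if (!is.numeric(iqr_k) || iqr_k <= 0) {
    stop("'iqr_k' must be positive", call. = FALSE)
  }
  structure(list(window_start = window_start, window_end = window_end,
                 ws_h = ws, we_h = we, rn_min = rn_min, iqr_k = iqr_k),
            class = "filter_config")
}

#' Convert stomatal conductance to m s-1
#'
#' Porometer/IRGA stomatal conductance in mol m-2 s-1 is converted to the
#' velocity unit m s-1 by dividing by the molar density of air
#' ([molar_density_air()]) at ambient temperature and pressure. Values
#' already in m s-1 pass through unchanged.
#'
#' @param value conductance value(s), in the unit named by `unit`.
#' @param unit `"mol_m2_s"` or `"m_s"` (recycled against `value`).
#' @param t_air air temperature, degC (used only for molar conversion).
#' @param p atmospheric pressure, kPa.
#' @param constants a [physical_constants()] bundle.
#' @return Stomatal conductance, m s-1.
#' @examples
#' gsw_to_ms(0.2, "mol_m2_s", t_air = 25, p = 98.726)  # ~0.00502
#' @export
gsw_to_ms <- function(value, unit, t_air, p,
                      constants = physical_constants()) {
  .check_finite(value, "value")
  if (any(value < 0)) stop("'value' must be non-negative", call. = FALSE)
  unit <- rep_len(as.character(unit), length(value))
  known <- unit %in% c("mol_m2_s", "m_s")
  if (!all(known)) {
    stop("unknown g_sw unit tag(s): ",
         paste(unique(unit[!known]), collapse = ", "),
         " (expected 'mol_m2_s' or 'm_s')", call. = FALSE)
  }
  out <- value
  conv <- unit == "mol_m2_s"
  if (any(conv)) {
    rho_mol <- molar_density_air(t_air, p, constants)
    rho_mol <- rep_len(rho_mol, length(value))
    out[conv] <- value[conv] / rho_mol[conv]
  }
  out
}

#' Aggregate leaf samples to a canopy stomatal conductance series
#'
#' Converts every leaf sample to m s-1 (via [gsw_to_ms()] at the concurrent
#' air temperature and the site pressure) and averages all samples sharing a
#' timestamp — east and west canopy sides enter with equal weight. Timestamps
#' represented by a single side are retained and flagged `"one_side_only"`.
#'
#' @param leaf data.frame with columns `timestamp`, `side`, `gsw_value`,
#'   `gsw_unit`.
#' @param meteo data.frame with columns `timestamp`, `t_air_c` supplying the
#'   concurrent temperature for the molar conversion.
#' @param site a [site_params()] object (supplies pressure).
#' @param constants a [physical_constants()] bundle.
#' @param cadence_s join cadence in seconds for matching leaf samples to
#'   meteo records (default hourly).
#' @return data.frame with columns `timestamp`, `gsw_m_s`, `n_samples`,
#'   `qc_flag`.
#' @export
aggregate_leaf_conductance <- function(leaf, meteo, site = site_params(),
                                       constants = physical_constants(),
                                       cadence_s = 3600) {
  need <- c("timestamp", "side", "gsw_value", "gsw_unit")
  miss <- setdiff(need, names(leaf))
  if (length(miss) > 0) {
    stop("leaf table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ts <- floor_to_cadence(leaf$timestamp, cadence_s)
  mt <- floor_to_cadence(meteo$timestamp, cadence_s)
  t_air <- meteo$t_air_c[match(ts, mt)]
  if (anyNA(t_air)) {
    stop("leaf sample(s) without a concurrent meteorological record; ",
         "cannot convert units", call. = FALSE)
  }
  gms <- gsw_to_ms(leaf$gsw_value, leaf$gsw_unit, t_air, site$pressure,
                   constants)
  key <- format_clock_time(ts)
  agg <- tapply(gms, key, mean)
  cnt <- tapply(gms, key, length)
  sides <- tapply(as.character(leaf$side), key,
                  function(s) length(unique(s)))
  out <- data.frame(
    timestamp = as_clock_time(names(agg)),
    gsw_m_s = as.numeric(agg),
    n_samples = as.integer(cnt),
    qc_flag = ifelse(as.integer(sides) < 2, "one_side_only", "ok"),
    stringsAsFactors = FALSE
  )
  out[order(out$timestamp), , drop = FALSE]
}

#' Daylight window and net-radiation exclusion filter
#'
#' Drops records collected outside the configured daylight window or under
#' low net radiation. Both criteria are enforced independently: a record is
#' retained only if its clock time lies inside
#' `[window_start, window_end]` (inclusive) **and** its net radiation is at
#' least `rn_min`. Every dropped record's reasons are reported in the
#' `"dropped"` attribute of the result.
#'
#' @param records data.frame with columns `timestamp` and `rn_mj_m2_h`.
#' @param cfg a [filter_config()] object.
#' @return The retained rows, with attribute `dropped`: a data.frame of
#'   `timestamp` and comma-separated `reason` for each excluded record.
#' @export
daylight_radiation_filter <- function(records, cfg = filter_config()) {
  need <- c("timestamp", "rn_mj_m2_h")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  hr <- clock_hour(records$timestamp)
  out_window <- hr < cfg$ws_h | hr > cfg$we_h
  low_rn <- records$rn_mj_m2_h < cfg$rn_min
  drop <- out_window | low_rn
  reason <- character(sum(drop))
  if (any(drop)) {
    reason <- apply(cbind(out_window[drop], low_rn[drop]), 1, function(z) {
      paste(c("outside_window", "rn_below_min")[z], collapse = ",")
    })
  }
  kept <- records[!drop, , drop = FALSE]
  if (nrow(kept) == 0) {
    warning("all records excluded by the daylight/radiation filter",
            call. = FALSE)
  }
  attr(kept, "dropped") <- data.frame(
    timestamp = as_clock_time(records$timestamp)[drop],
    reason = reason, stringsAsFactors = FALSE
  )
  kept
}

#' Interquartile-range outlier mask
#'
#' Flags values outside the Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]`.
#' Quartiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`); pass another `type` to change it.
#'
#' @param values numeric vector (at least 4 finite values).
#' @param k fence multiplier (default 1.5).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return Logical vector, `TRUE` where the value is an outlier (`NA` inputs
#'   yield `NA`).
#' @examples
#' iqr_outlier_mask(c(1, 2, 3, 4, 100))
#' @export
iqr_outlier_mask <- function(values, k = 1.5, type = 7) {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  finite <- values[is.finite(values)]
  if (length(finite) < 4) {
    stop("insufficient data: need at least 4 finite values for IQR screening",
         call. = FALSE)
  }
  if (!is.numeric(k) || k <= 0) stop("'k' must be positive", call. = FALSE)
  q <- stats::quantile(finite, probs = c(0.25, 0.75), names = FALSE,
                       type = type)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Align meteorology, leaf conductance and flux series
#'
#' Floors every timestamp to the join cadence (hourly by default), averages
#' finer-cadence meteorological variables within each cadence bin, and inner
#' joins the three tables on timestamp. Unmatched timestamps are reported in
#' the `"unmatched"` attribute.
#'
#' @param meteo data.frame with `timestamp`, `t_air_c`, `rh_pct`,
#'   `rn_mj_m2_h`, `u_m_s`.
#' @param leaf_agg data.frame with `timestamp`, `gsw_m_s` (output of
#'   [aggregate_leaf_conductance()]).
#' @param flux data.frame with `timestamp`, `ec_mm_h`.
#' @param cadence_s join cadence, seconds (default 3600).
#' @return The joined analysis table with one row per common timestamp and
#'   columns `timestamp`, `t_air_c`, `rh_pct`, `rn_mj_m2_h`, `u_m_s`,
#'   `gsw_m_s`, `ec_mm_h` (plus `qc_flag` from the leaf aggregation when
#'   present); attribute `unmatched` lists timestamps present in some but not
#'   all inputs.
#' @export
align_records <- function(meteo, leaf_agg, flux, cadence_s = 3600) {
  bin_mean <- function(df, vars) {
    ts <- floor_to_cadence(df$timestamp, cadence_s)
    key <- format_clock_time(ts)
    out <- data.frame(timestamp = as_clock_time(unique(key[order(ts)])))
    for (v in vars) {
      out[[v]] <- as.numeric(tapply(df[[v]], key, mean)[
        format_clock_time(out$timestamp)])
    }
    out
  }
  m <- bin_mean(meteo, c("t_air_c", "rh_pct", "rn_mj_m2_h", "u_m_s"))
  l <- leaf_agg
  l$timestamp <- floor_to_cadence(l$timestamp, cadence_s)
  f <- bin_mean(flux, "ec_mm_h")

  j <- merge(m, l, by = "timestamp")
  j <- merge(j, f, by = "timestamp")
  if (nrow(j) == 0) {
    stop("empty join: the input series share no timestamps at this cadence",
         call. = FALSE)
  }
  all_ts <- unique(c(format_clock_time(m$timestamp),
                     format_clock_time(l$timestamp),
                     format_clock_time(f$timestamp)))
  unmatched <- setdiff(all_ts, format_clock_time(j$timestamp))
  if (length(unmatched) > 0) {
    message(length(unmatched), " timestamp(s) unmatched across inputs")
  }
  j <- j[order(j$timestamp), , drop = FALSE]
  rownames(j) <- NULL
  attr(j, "unmatched") <- unmatched
  j
}
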