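# Fixed CSV schema: exact lowercase column names, one header row, ISO-8601
# local-time timestamps. One list entry per table kind.
.schema <- list(
  meteo = c("timestamp", "t_air_c", "rh_pct", "rn_mj_m2_h", "u_m_s"),
  leaf = c("timestamp", "side", "gsw_value", "gsw_unit"),
  flux = c("timestamp", "ec_mm_h"),
  conductance = c("timestamp", "gc_m_s", "provenance", "qc_flag"),
  truth = c("timestamp", "gc_true_m_s")
)

.read_table <- function(path, kind) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- .schema[[kind]]
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

# Row-level validation; returns list(rows = kept df, rejected = report df).
.validate_rows <- function(df, kind, path) {
  ts <- suppressWarnings(as_clock_time(df$timestamp))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(ts)] <- "unparseable_timestamp"
  if (kind == "meteo") {
    bad_rh <- !is.na(ts) & (!is.finite(df$rh_pct) | df$rh_pct < 0 |
                              df$rh_pct > 100)
    reason[bad_rh] <- "rh_out_of_range"
    bad_num <- !is.na(ts) & is.na(reason) &
      (!is.finite(df$t_air_c) | !is.finite(df$rn_mj_m2_h) |
         !is.finite(df$u_m_s) | df$u_m_s < 0)
    reason[bad_num] <- "nonfinite_or_negative_value"
  }
  if (kind == "leaf") {
    bad <- !is.na(ts) & (!is.finite(df$gsw_value) | df$gsw_value < 0)
    reason[bad] <- "gsw_negative_or_nonfinite"
    bad_u <- !is.na(ts) & is.na(reason) &
      !(df$gsw_unit %in% c("mol_m2_s", "m_s"))
    reason[bad_u] <- "unknown_gsw_unit"
  }
  if (kind == "flux") {
    bad <- !is.na(ts) & (!is.finite(df$ec_mm_h) | df$ec_mm_h < 0)
    reason[bad] <- "ec_negative_or_nonfinite"
  }
  rej <- which(!is.na(reason))
  rejected <- data.frame(
    file = rep(basename(path), length(rej)),
    line = rej + 1L,  # header is line 1
    reason = reason[rej], stringsAsFactors = FALSE
  )
  kept <- df[setdiff(seq_len(nrow(df)), rej), , drop = FALSE]
  kept$timestamp <- as_clock_time(kept$timestamp)
  rownames(kept) <- NULL
  list(rows = kept, rejected = rejected)
}

#' Read a raw dataset bundle
#'
#' Reads and validates the three raw CSV tables (meteorology, leaf samples,
#' transpiration flux) plus an optional site configuration. Column names must
#' match the schema exactly (`meteo`: `timestamp, t_air_c, rh_pct,
#' rn_mj_m2_h, u_m_s`; `leaf`: `timestamp, side, gsw_value, gsw_unit`;
#' `flux`: `timestamp, ec_mm_h`). Malformed rows (unparseable timestamp,
#' out-of-range humidity, negative flux, unknown unit tag) are rejected with
#' a per-row reason and line number, collected in the bundle's `qc` table.
#'
#' @param dir directory containing `meteo.csv`, `leaf.csv`, `flux.csv` and
#'   optionally `site.cfg`; alternatively pass explicit `paths`.
#' @param paths optional named character vector/list overriding the default
#'   file names (names `meteo`, `leaf`, `flux`, and optionally `site`).
#' @return An object of class `raw_bundle`: list with `meteo`, `leaf`,
#'   `flux` data.frames, `site` ([site_params()] or `NULL`), and `qc`
#'   (rejected-row report).
#' @export
read_raw <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    if (is.null(dir)) stop("supply 'dir' or 'paths'", call. = FALSE)
    paths <- list(meteo = file.path(dir, "meteo.csv"),
                  leaf = file.path(dir, "leaf.csv"),
                  flux = file.path(dir, "flux.csv"))
    sc <- file.path(dir, "site.cfg")
    if (file.exists(sc)) paths$site <- sc
  }
  out <- list()
  qc <- list()
  for (kind in c("meteo", "leaf", "flux")) {
    v <- .validate_rows(.read_table(paths[[kind]], kind), kind, paths[[kind]])
    out[[kind]] <- v$rows
    qc[[kind]] <- v$rejected
  }
  out$site <- if (!is.null(paths$site)) site_from_config(paths$site) else NULL
  out$qc <- do.call(rbind, qc)
  rownames(out$qc) <- NULL
  structure(out, class = "raw_bundle")
}

#' Write a synthetic campaign as a raw dataset bundle
#'
#' Writes `meteo.csv`, `leaf.csv`, `flux.csv`, the ground-truth
#' `truth.csv`, and the site configuration `site.cfg` into `dir`, in the
#' fixed CSV schema read back by [read_raw()].
#'
#' @param campaign a [generate_campaign()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    df$timestamp <- format_clock_time(df$timestamp)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(campaign$meteo, "meteo.csv")
  wr(campaign$leaf, "leaf.csv")
  wr(campaign$flux, "flux.csv")
  wr(campaign$truth, "truth.csv")
  s <- campaign$site
  write_config(list(elevation = s$elevation, pressure = s$pressure,
                    z_m = s$z_m, h = s$h, lai = s$lai),
               file.path(dir, "site.cfg"))
  invisible(dir)
}

#' Write a conductance series as CSV
#'
#' @param series a [conductance_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_conductance_csv <- function(series, path) {
  df <- as.data.frame(series)
  df$timestamp <- format_clock_time(df$timestamp)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a conductance series from CSV
#'
#' @param path CSV file in the conductance schema
#'   (`timestamp, gc_m_s, provenance, qc_flag`).
#' @return A [conductance_series()].
#' @export
read_conductance_csv <- function(path) {
  df <- .read_table(path, "conductance")
  conductance_series(df$timestamp, df$gc_m_s, df$provenance[1], df$qc_flag)
}

#' Plain-text key-value configuration
#'
#' `read_config()` parses `key = value` lines (one per line, `#` comments,
#' dotted keys allowed); numeric-looking values are returned as numbers.
#' `write_config()` is its inverse. `site_from_config()` builds a
#' [site_params()] from the keys `elevation`, `z_m`, `h`, `lai` and
#' optionally `pressure`.
#'
#' @param path configuration file path.
#' @param x named list to write.
#' @return `read_config`: named list. `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) {
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    }
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  lines <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    paste0(nm, " = ", if (is.numeric(v)) format(v, digits = 15) else v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_config
#' @export
site_from_config <- function(path) {
  cfg <- read_config(path)
  args <- list()
  for (nm in c("elevation", "z_m", "h", "lai", "pressure")) {
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  }
  do.call(site_params, args)
}

#' Run the full analysis pipeline on a raw bundle
#'
#' Raw tables to evaluation report in one call: applies the daylight and
#' radiation filter to the meteorology ([daylight_radiation_filter()]),
#' converts and aggregates the leaf samples
#' ([aggregate_leaf_conductance()]), aligns the three series
#' ([align_records()]), computes the estimated and observed conductance
#' series ([conductance_pipeline()]), and evaluates their agreement
#' ([evaluate_model()]).
#'
#' @param bundle a [read_raw()] bundle (or a [generate_campaign()] campaign).
#' @param site a [site_params()] object; defaults to the bundle's own site
#'   when present.
#' @param filter_cfg a [filter_config()]; set `apply_filter = FALSE` to skip
#'   the exclusion rules.
#' @param apply_filter logical; apply the daylight/radiation filter?
#' @param u1_mode U1 convention for the report.
#' @param constants a [physical_constants()] bundle.
#' @return A list with `aligned` (analysis table), `estimated` and `observed`
#'   ([conductance_series()]), `report` (`evaluation_report`), and `qc`
#'   (per-record exclusion reasons from filtering and conductance
#'   computation).
#' @export
run_pipeline <- function(bundle, site = NULL, filter_cfg = filter_config(),
                         apply_filter = TRUE,
                         u1_mode = c("table_interpolation", "exact_normal"),
                         constants = physical_constants()) {
  u1_mode <- match.arg(u1_mode)
  if (inherits(bundle, "campaign")) {
    site <- if (is.null(site)) bundle$site else site
    bundle <- list(meteo = bundle$meteo, leaf = bundle$leaf,
                   flux = bundle$flux, site = site)
  }
  if (is.null(site)) site <- bundle$site
  if (is.null(site)) site <- site_params()

  meteo <- bundle$meteo
  dropped <- NULL
  if (apply_filter) {
    meteo <- daylight_radiation_filter(meteo, filter_cfg)
    dropped <- attr(meteo, "dropped")
  }
  leaf_agg <- aggregate_leaf_conductance(bundle$leaf, bundle$meteo, site,
                                         constants)
  aligned <- align_records(meteo, leaf_agg, bundle$flux)
  series <- conductance_pipeline(aligned, site, constants)
  report <- evaluate_model(series$observed, series$estimated,
                           u1_mode = u1_mode)
  qc <- data.frame(timestamp = character(0), reason = character(0),
                   stringsAsFactors = FALSE)
  if (!is.null(dropped) && nrow(dropped) > 0) {
    qc <- rbind(qc, data.frame(timestamp = format_clock_time(dropped$timestamp),
                               reason = dropped$reason))
  }
  bad <- series$estimated$qc_flag != "ok" | series$observed$qc_flag != "ok"
  if (any(bad)) {
    qc <- rbind(qc, data.frame(
      timestamp = format_clock_time(series$estimated$timestamp[bad]),
      reason = paste0(series$estimated$qc_flag[bad], "/",
                      series$observed$qc_flag[bad])))
  }
  list(aligned = aligned, estimated = series$estimated,
       observed = series$observed, report = report, qc = qc)
}
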