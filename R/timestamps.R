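# Timestamps are local clock time without timezone; they are parsed into
# POSIXct with tz = "UTC" purely as a fixed internal representation so that
# arithmetic and formatting are independent of the host machine's zone.

#' Parse local clock timestamps
#'
#' Accepts POSIXct, Date, or ISO-8601 strings (`"YYYY-MM-DD HH:MM[:SS]"`,
#' `"T"` separator allowed) and returns POSIXct in a fixed internal timezone.
#'
#' @param x timestamps to parse.
#' @return POSIXct vector; unparseable elements become `NA` with a warning.
#' @export
as_clock_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) return(as.POSIXct(x, tz = "UTC"))
  s <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(s)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(s[todo], fmt, tz = "UTC"))
  }
  if (any(is.na(out) & !is.na(x))) {
    warning(sum(is.na(out) & !is.na(x)), " unparseable timestamp(s)",
            call. = FALSE)
  }
  out
}

#' Format timestamps for the CSV schema
#'
#' @param x POSIXct timestamps.
#' @return ISO-8601 strings, local clock time without timezone suffix.
#' @export
format_clock_time <- function(x) {
  format(as_clock_time(x), "%Y-%m-%d %H:%M:%S")
}

# Hour-of-day as decimal (e.g. 10:30 -> 10.5).
clock_hour <- function(x) {
  x <- as_clock_time(x)
  as.numeric(format(x, "%H")) + as.numeric(format(x, "%M")) / 60 +
    as.numeric(format(x, "%S")) / 3600
}

# Parse "HH:MM" clock strings to decimal hours.
parse_clock <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || anyNA(suppressWarnings(as.numeric(parts)))) {
    stop(sprintf("invalid clock time '%s'; expected HH:MM", s), call. = FALSE)
  }
  as.numeric(parts[1]) + as.numeric(parts[2]) / 60
}

# Floor timestamps to a cadence in seconds (3600 = hourly).
floor_to_cadence <- function(x, cadence_s = 3600) {
  x <- as_clock_time(x)
  as.POSIXct(floor(as.numeric(x) / cadence_s) * cadence_s,
             origin = "1970-01-01", tz = "UTC")
}
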