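#' @importFrom stats rbinom rexp rpois runif setNames sd
#' @importFrom utils URLdecode URLencode head read.csv tail write.csv
#' @importFrom data.table data.table as.data.table setorder
NULL

# makes [.data.table use data.table semantics inside this package
.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse ISO-8601 timestamps to epoch seconds
#'
#' Accepts `"YYYY-MM-DDTHH:MM:SSZ"` or an explicit numeric offset
#' (`+hh:mm`/`+hhmm`). Numeric input is passed through unchanged, so every
#' user-facing function can take either representation. Unparseable strings
#' yield `NA` so callers can report the offending line.
#'
#' @param x character or numeric vector.
#' @return numeric vector of seconds since the Unix epoch (`NA` on failure).
#' @export
parse_timestamp <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  nonempty <- !is.na(x) & nzchar(trimws(x))
  if (!any(nonempty)) return(out)
  xs <- trimws(x[nonempty])
  # "Z" suffix: parse as UTC; otherwise rely on %z offset parsing
  zulu <- grepl("Z$", xs)
  res <- rep(NA_real_, length(xs))
  if (any(zulu)) {
    t <- as.POSIXct(sub("Z$", "", xs[zulu]),
                    format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    res[zulu] <- as.numeric(t)
  }
  if (any(!zulu)) {
    raw <- xs[!zulu]
    # strptime's %z wants +hhmm, not +hh:mm
    raw <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", raw)
    t <- as.POSIXct(raw, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
    res[!zulu] <- as.numeric(t)
  }
  out[nonempty] <- res
  out
}

#' Format epoch seconds as ISO-8601 UTC
#'
#' @param t numeric vector, seconds since the Unix epoch.
#' @return character vector `"YYYY-MM-DDTHH:MM:SSZ"` (`""` for `NA`).
#' @export
format_timestamp <- function(t) {
  out <- rep("", length(t))
  ok <- !is.na(t)
  out[ok] <- format(as.POSIXct(round(t[ok]), origin = "1970-01-01", tz = "UTC"),
                    "%Y-%m-%dT%H:%M:%SZ")
  out
}

# Half-up rounding at `digits` decimals, used for report-style output.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_hp <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_hp("`%s` must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_hp("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
            if (strict_lower) "(" else "[", lower, upper,
            if (strict_upper) ")" else "]")
  invisible(x)
}
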