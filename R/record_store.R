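# File-backed store for visitors, venues and check-in/check-out records.
# A record collection is a plain data.frame with columns
#   visitor_id, venue_id, t_in, t_out, reason, liability
# where t_in/t_out are epoch seconds (t_out NA for a still-open session) and
# liability is the visitor's score phi in [0,1] (NA when unknown). Sessions
# are half-open intervals [t_in, t_out): a visitor present at exactly t_out
# has departed.

CHECKIN_COLUMNS <- c("visitor_id", "venue_id", "check_in_time",
                     "check_out_time", "reason", "liability")

#' Construct a check-in record collection
#'
#' Validates the record invariants (non-empty identifiers, `t_out >= t_in`
#' where present, `liability` in \[0,1\]) and returns the canonical
#' data.frame ordered by check-in time.
#'
#' @param visitor_id,venue_id character vectors of opaque identifiers.
#' @param t_in,t_out check-in / check-out times (epoch seconds or ISO-8601
#'   strings; `t_out` may be `NA` for open sessions).
#' @param reason optional free-text reason for the visit.
#' @param liability optional liability score in \[0,1\].
#' @return data.frame with columns `visitor_id`, `venue_id`, `t_in`, `t_out`,
#'   `reason`, `liability`, ordered by `t_in`.
#' @export
checkin_records <- function(visitor_id, venue_id, t_in, t_out = NA,
                            reason = NA, liability = NA) {
  n <- length(visitor_id)
  rec <- data.frame(
    visitor_id = as.character(visitor_id),
    venue_id   = as.character(venue_id),
    t_in       = parse_timestamp(t_in),
    t_out      = parse_timestamp(rep_len(t_out, n)),
    reason     = as.character(rep_len(reason, n)),
    liability  = as.numeric(rep_len(liability, n)),
    stringsAsFactors = FALSE
  )
  validate_checkins(rec)
  rec[order(rec$t_in), , drop = FALSE]
}

validate_checkins <- function(rec, line_offset = NULL) {
  where <- function(i) {
    if (is.null(line_offset)) sprintf("record %d", i)
    else sprintf("line %d", i + line_offset)
  }
  bad <- which(is.na(rec$visitor_id) | !nzchar(rec$visitor_id))
  if (length(bad)) stop_hp("empty visitor_id at %s", where(bad[1]))
  bad <- which(is.na(rec$venue_id) | !nzchar(rec$venue_id))
  if (length(bad)) stop_hp("empty venue_id at %s", where(bad[1]))
  bad <- which(is.na(rec$t_in))
  if (length(bad)) stop_hp("malformed check_in_time at %s", where(bad[1]))
  bad <- which(!is.na(rec$t_out) & rec$t_out < rec$t_in)
  if (length(bad))
    stop_hp("check_out_time earlier than check_in_time at %s", where(bad[1]))
  bad <- which(!is.na(rec$liability) &
                 (rec$liability < 0 | rec$liability > 1))
  if (length(bad)) stop_hp("liability outside [0,1] at %s", where(bad[1]))
  invisible(rec)
}

#' Read check-in records from CSV or JSON-lines
#'
#' The CSV schema is
#' `visitor_id,venue_id,check_in_time,check_out_time,reason,liability`
#' with ISO-8601 timestamps; `check_out_time`, `reason` and `liability` may be
#' empty. JSON-lines files carry one object per line with the same keys.
#' Malformed rows raise an error naming the offending line.
#'
#' @param path file to read.
#' @param format `"csv"` or `"jsonl"`.
#' @return records ordered by `t_in` (see [checkin_records()]).
#' @export
read_checkins <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_hp("file not found: %s", path)
  if (format == "csv") {
    raw <- read.csv(path, colClasses = "character", check.names = FALSE)
    if (!identical(names(raw), CHECKIN_COLUMNS))
      stop_hp("unexpected CSV header in %s: expected %s", path,
              paste(CHECKIN_COLUMNS, collapse = ","))
    line_offset <- 1L  # header line
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    objs <- lapply(seq_along(lines), function(i) {
      o <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop_hp(
                      "malformed JSON at line %d: %s", i, conditionMessage(e)))
      unknown <- setdiff(names(o), CHECKIN_COLUMNS)
      if (length(unknown))
        stop_hp("unknown key '%s' at line %d", unknown[1], i)
      o
    })
    get_chr <- function(o, k) {
      v <- o[[k]]
      if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
    }
    raw <- data.frame(
      visitor_id     = vapply(objs, get_chr, "", "visitor_id"),
      venue_id       = vapply(objs, get_chr, "", "venue_id"),
      check_in_time  = vapply(objs, get_chr, "", "check_in_time"),
      check_out_time = vapply(objs, get_chr, "", "check_out_time"),
      reason         = vapply(objs, get_chr, "", "reason"),
      liability      = vapply(objs, get_chr, "", "liability"),
      stringsAsFactors = FALSE
    )
    line_offset <- 0L
  }
  if (nrow(raw) == 0) return(empty_checkins())
  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA, x)
  t_in <- parse_timestamp(raw$check_in_time)
  t_out <- parse_timestamp(blank_to_na(raw$check_out_time))
  rec <- data.frame(
    visitor_id = raw$visitor_id,
    venue_id   = raw$venue_id,
    t_in       = t_in,
    t_out      = t_out,
    reason     = as.character(blank_to_na(raw$reason)),
    liability  = as.numeric(blank_to_na(raw$liability)),
    stringsAsFactors = FALSE
  )
  validate_checkins(rec, line_offset = line_offset)
  rec[order(rec$t_in), , drop = FALSE]
}

empty_checkins <- function() {
  data.frame(visitor_id = character(), venue_id = character(),
             t_in = numeric(), t_out = numeric(), reason = character(),
             liability = numeric(), stringsAsFactors = FALSE)
}

#' Write check-in records to CSV or JSON-lines
#'
#' Timestamps are serialized as ISO-8601 UTC at one-second resolution, so a
#' collection with integer-second timestamps round-trips field-for-field
#' through [read_checkins()]. Field order is fixed, making output byte-stable.
#'
#' @param records record collection (see [checkin_records()]).
#' @param path file to write.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_checkins <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  validate_checkins(records)
  num_chr <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                     scientific = FALSE,
                                                     digits = 15))
  out <- data.frame(
    visitor_id     = records$visitor_id,
    venue_id       = records$venue_id,
    check_in_time  = format_timestamp(records$t_in),
    check_out_time = format_timestamp(records$t_out),
    reason         = ifelse(is.na(records$reason), "", records$reason),
    liability      = num_chr(records$liability),
    stringsAsFactors = FALSE
  )
  if (format == "csv") {
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      o <- as.list(out[i, , drop = FALSE])
      o <- o[nzchar(unlist(o))]  # omit empty optional fields
      as.character(jsonlite::toJSON(o, auto_unbox = TRUE))
    }, "")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Venue registry I/O
#'
#' `venues.csv` has columns `venue_id,capacity`; capacity is the venue's
#' maximum occupancy `N_c` (persons, at least 1) set by the venue manager.
#'
#' @param path file to read or write.
#' @param venues data.frame with columns `venue_id` and `capacity`.
#' @return `read_venues()` returns the registry data.frame.
#' @export
read_venues <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("venue_id", "capacity") %in% names(raw)))
    stop_hp("venue registry %s must have columns venue_id,capacity", path)
  raw$venue_id <- as.character(raw$venue_id)
  raw$capacity <- as.integer(raw$capacity)
  if (any(is.na(raw$capacity) | raw$capacity < 1))
    stop_hp("venue capacity must be a positive integer")
  raw
}

#' @rdname read_venues
#' @export
write_venues <- function(venues, path) {
  write.csv(venues[, c("venue_id", "capacity")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Venue occupancy at a time point
#'
#' Counts sessions for `venue_id` whose half-open interval `[t_in, t_out)`
#' covers `t`; open sessions (no check-out yet) count as present. A visitor
#' whose check-out time equals `t` has departed.
#'
#' @param records record collection.
#' @param venue_id venue to count.
#' @param t time point(s), epoch seconds or ISO-8601.
#' @return non-negative integer vector, one count per element of `t`.
#' @export
occupancy <- function(records, venue_id, t) {
  t <- parse_timestamp(t)
  sub <- records[records$venue_id == venue_id, , drop = FALSE]
  vapply(t, function(tt) {
    sum(sub$t_in <= tt & (is.na(sub$t_out) | sub$t_out > tt))
  }, integer(1))
}

#' QR payload encoding for venue identifiers
#'
#' Each venue is identified by a URI-style payload
#' `healthpass://venue/<id>`; reserved characters in the identifier are
#' percent-encoded. Image rendering is out of scope — the payload string is
#' what a QR generator would encode.
#'
#' @param venue_id non-empty venue identifier.
#' @param payload payload string produced by `encode_qr_payload()`.
#' @return the payload string, or the recovered venue identifier.
#' @export
encode_qr_payload <- function(venue_id) {
  if (!is.character(venue_id) || length(venue_id) != 1L ||
      is.na(venue_id) || !nzchar(venue_id))
    stop_hp("venue_id must be a non-empty string")
  paste0("healthpass://venue/", URLencode(venue_id, reserved = TRUE))
}

#' @rdname encode_qr_payload
#' @export
decode_qr_payload <- function(payload) {
  prefix <- "healthpass://venue/"
  if (!is.character(payload) || length(payload) != 1L || is.na(payload) ||
      !startsWith(payload, prefix))
    stop_hp("not a healthpass venue payload: %s",
            if (length(payload) == 1L) as.character(payload) else "<vector>")
  id <- URLdecode(substring(payload, nchar(prefix) + 1L))
  if (!nzchar(id)) stop_hp("payload carries an empty venue identifier")
  id
}
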