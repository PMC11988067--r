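FIX_CSV_COLUMNS <- c("animal_id", "gmt_time", "local_time", "lat", "lon",
                     "easting", "northing", "altitude_m", "temp_c",
                     "voltage", "dop", "satellites", "x", "y", "z")

#' Write / read collar fixes as CSV
#'
#' The on-disk schema is the collar field set: `animal_id`, `gmt_time`
#' (ISO-8601 UTC), `local_time`, `lat`, `lon`, `easting`, `northing`,
#' `altitude_m`, `temp_c`, `voltage`, `dop`, `satellites`, `x`, `y`, `z`.
#' Any extra in-memory columns (simulation truth, cleaning bookkeeping)
#' are not written.
#'
#' @param fixes Fix data.frame.
#' @param path File path.
#' @return `path` invisibly (writer); fix data.frame with POSIXct
#'   `gmt_time` (reader).
#' @export
write_fixes_csv <- function(fixes, path) {
  out <- fixes[, FIX_CSV_COLUMNS]
  out$gmt_time <- format(fixes$gmt_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes_csv
#' @export
read_fixes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$gmt_time <- as.POSIXct(df$gmt_time, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  df
}

#' Write / read behavior transcription events as CSV
#'
#' Schema: `animal_id`, `start_local`, `end_local`, `behavior`, `posture`,
#' `state`. Local times are stored as ISO-8601 at the configured fixed
#' offset from GMT.
#'
#' @param events Event data.frame with POSIXct `start`/`end` in UTC.
#' @param path File path.
#' @param tz_offset_h Local offset from GMT in hours (default -6).
#' @return `path` invisibly (writer); event data.frame with UTC POSIXct
#'   `start`/`end` (reader).
#' @export
write_events_csv <- function(events, path, tz_offset_h = -6) {
  out <- data.frame(
    animal_id = events$animal_id,
    start_local = format(events$start + tz_offset_h * 3600,
                         "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    end_local = format(events$end + tz_offset_h * 3600,
                       "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    behavior = events$behavior,
    posture = events$posture %||% "NA",
    state = to_state(events$behavior,
                     (as.numeric(events$end) - as.numeric(events$start)) / 60)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, tz_offset_h = -6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    animal_id = df$animal_id,
    start = as.POSIXct(df$start_local, format = "%Y-%m-%dT%H:%M:%S",
                       tz = "UTC") - tz_offset_h * 3600,
    end = as.POSIXct(df$end_local, format = "%Y-%m-%dT%H:%M:%S",
                     tz = "UTC") - tz_offset_h * 3600,
    behavior = df$behavior,
    posture = df$posture
  )
}
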