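# Recognised behavioral event kinds. Licks carry the spout in the kind
# itself; rfid_scan is the only kind that carries a tag.
EVENT_KINDS <- c(
  "lick_active", "lick_inactive", "motion", "reward",
  "cue_on", "cue_off", "rfid_scan", "session_start", "session_end"
)

#' Recognised event kinds
#'
#' The vocabulary of the behavioral event stream: licks on the active and
#' inactive spout, motion-sensor triggers, reward deliveries, cue-light
#' on/off, RFID scans and the session boundary markers.
#'
#' @return Character vector of the valid `kind` values.
#' @export
event_kinds <- function() EVENT_KINDS

#' Validate an RFID tag string
#'
#' Implanted glass RFID transponders encode a twelve-character hexadecimal
#' identifier. A tag is valid iff it is exactly 12 hexadecimal characters
#' (case-insensitive).
#'
#' @param text Character vector of candidate tags.
#' @return Logical vector, one element per input.
#' @examples
#' validate_tag("0A1B2C3D4E5F")  # TRUE
#' validate_tag("0A1B2C3D4E5")   # FALSE: 11 characters
#' validate_tag("0A1B2C3D4EZZ")  # FALSE: not hexadecimal
#' @export
validate_tag <- function(text) {
  if (length(text) == 0L) return(logical(0))
  !is.na(text) & grepl("^[0-9A-Fa-f]{12}$", text)
}

#' Build an event table
#'
#' Assembles a tibble of timestamped behavioral events in the package's
#' canonical layout: `time_s` (seconds since session start), `kind` (one of
#' [event_kinds()]) and `tag` (12-hex RFID identifier, `NA` except for
#' `rfid_scan` rows).
#'
#' @param time_s Numeric vector of non-negative event times, seconds.
#' @param kind Character vector of event kinds, recycled if length 1.
#' @param tag Character vector of RFID tags (`NA` where absent).
#' @return A tibble with columns `time_s`, `kind`, `tag`.
#' @export
events_frame <- function(time_s = numeric(), kind = character(), tag = NA_character_) {
  n <- length(time_s)
  if (length(kind) == 1L) kind <- rep(kind, n)
  if (length(tag) == 1L) tag <- rep(tag, n)
  tibble::tibble(
    time_s = as.numeric(time_s),
    kind = as.character(kind),
    tag = as.character(tag)
  )
}

# Validates an event table. Returns invisibly or stops with a message
# naming the first offending row.
validate_events <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("time_s", "kind", "tag")
  if (!all(need %in% names(events))) {
    stop("event table must have columns time_s, kind, tag", call. = FALSE)
  }
  if (nrow(events) == 0L) return(invisible(events))
  bad <- which(!(events$kind %in% EVENT_KINDS))
  if (length(bad)) {
    stop(sprintf("unknown event kind '%s' at event %d", events$kind[bad[1]], bad[1]),
         call. = FALSE)
  }
  bad <- which(is.na(events$time_s) | events$time_s < 0)
  if (length(bad)) {
    stop(sprintf("negative or missing time at event %d", bad[1]), call. = FALSE)
  }
  if (is.unsorted(events$time_s)) {
    bad <- which(diff(events$time_s) < 0)[1] + 1L
    stop(sprintf("event times not non-decreasing at event %d", bad), call. = FALSE)
  }
  is_scan <- events$kind == "rfid_scan"
  bad <- which(is_scan & !validate_tag(events$tag))
  if (length(bad)) {
    stop(sprintf("rfid_scan without a valid 12-hex tag at event %d", bad[1]),
         call. = FALSE)
  }
  bad <- which(!is_scan & !is.na(events$tag))
  if (length(bad)) {
    stop(sprintf("tag present on non-rfid_scan event %d", bad[1]), call. = FALSE)
  }
  invisible(events)
}

#' Construct a session record
#'
#' A session record bundles one animal's session: its RFID identity, the
#' reinforcement schedule in force, absolute start/end times, the
#' time-ordered event log (times in seconds since session start) and the
#' reward count (always recomputed from the events).
#'
#' @param subject_tag 12-character hexadecimal RFID tag of the subject.
#' @param schedule A [schedule_spec()].
#' @param events Event tibble as built by [events_frame()]; must start with
#'   a `session_start` row and end with a `session_end` row.
#' @param start_time Absolute session start, `POSIXct` (coerced to UTC).
#' @param seed Optional integer seed recorded for reproducibility.
#' @return An object of class `session_record`.
#' @seealso [write_event_log()], [read_event_log()], [run_session()]
#' @export
session_record <- function(subject_tag, schedule, events,
                           start_time = as.POSIXct("2016-07-01 09:00:00", tz = "UTC"),
                           seed = NULL) {
  stopifnot(inherits(schedule, "schedule_spec"))
  if (!isTRUE(validate_tag(subject_tag))) {
    stop("subject_tag must be a 12-character hexadecimal string", call. = FALSE)
  }
  validate_events(events)
  if (nrow(events) < 2L ||
      events$kind[1] != "session_start" ||
      events$kind[nrow(events)] != "session_end") {
    stop("events must start with session_start and end with session_end",
         call. = FALSE)
  }
  start_time <- as.POSIXct(start_time, tz = "UTC")
  attr(start_time, "tzone") <- "UTC"
  rec <- structure(
    list(
      subject_tag = toupper(subject_tag),
      schedule = schedule,
      start_time = start_time,
      end_time = start_time + events$time_s[nrow(events)],
      events = events,
      rewards = sum(events$kind == "reward"),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "session_record"
  )
  rec
}

#' @export
print.session_record <- function(x, ...) {
  counts <- table(factor(x$events$kind, levels = EVENT_KINDS))
  cat(sprintf("<session_record> subject %s, schedule %s\n",
              x$subject_tag, format(x$schedule, compact = TRUE)))
  cat(sprintf("  start %s, duration %.1f s, %d events\n",
              format(x$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
              x$events$time_s[nrow(x$events)], nrow(x$events)))
  cat(sprintf("  licks active/inactive %d/%d, rewards %d, motion %d\n",
              counts[["lick_active"]], counts[["lick_inactive"]],
              x$rewards, counts[["motion"]]))
  invisible(x)
}

# Seconds-since-start are stored as decimal text with enough fractional
# digits for the decimal to identify the double uniquely (18 significant
# digits), so read(write(x)) is exact. Trailing zeros are trimmed but at
# least 3 fractional digits (millisecond resolution) are kept.
format_time_s <- function(t) {
  intdig <- ifelse(t >= 1, floor(log10(t)) + 1, 0)
  d <- as.integer(pmax(3, 18 - intdig))
  s <- sprintf("%.*f", d, t)
  s <- sub("(\\.\\d{3}\\d*?)0+$", "\\1", s)
  s
}

#' Write a session event log as CSV
#'
#' Serializes a [session_record()] to the package's on-disk log format: a
#' block of `#`-prefixed metadata lines (subject tag, schedule parameters,
#' absolute start/end times, seed) followed by a `time_s,kind,tag` CSV body.
#' The format round-trips losslessly through [read_event_log()].
#'
#' @param record A valid `session_record`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  validate_events(record$events)
  sp <- record$schedule
  meta <- c(
    "# lickometry event log v1",
    sprintf("# subject_tag: %s", record$subject_tag),
    sprintf("# start_time_epoch: %.17g", as.numeric(record$start_time)),
    sprintf("# schedule_family: %s", sp$family),
    sprintf("# schedule_ratio: %d", sp$ratio),
    sprintf("# schedule_pr_step: %d", sp$pr_step),
    sprintf("# schedule_timeout_s: %s", format_time_s(sp$timeout_s)),
    sprintf("# schedule_cue_s: %s", format_time_s(sp$cue_s)),
    sprintf("# schedule_session_s: %s", format_time_s(sp$session_s)),
    sprintf("# schedule_pr_idle_stop_s: %s", format_time_s(sp$pr_idle_stop_s))
  )
  if (!is.null(sp$vr_draws)) {
    meta <- c(meta, sprintf("# schedule_vr_draws: %s",
                            paste(sp$vr_draws, collapse = " ")))
  }
  if (!is.null(record$seed)) {
    meta <- c(meta, sprintf("# seed: %d", record$seed))
  }
  ev <- record$events
  body <- sprintf("%s,%s,%s", format_time_s(ev$time_s), ev$kind,
                  ifelse(is.na(ev$tag), "", ev$tag))
  con <- file(path, open = "wb")  # fixed \n endings for byte-reproducibility
  on.exit(close(con))
  writeLines(c(meta, "time_s,kind,tag", body), con, sep = "\n")
  invisible(path)
}

#' Read a session event log from CSV
#'
#' Parses a log written by [write_event_log()] (or by compatible acquisition
#' software) and returns a validated [session_record()]. Malformed rows,
#' unknown event kinds and non-monotone times are rejected with the
#' offending line number.
#'
#' @param path Path to an event-log CSV.
#' @return A `session_record`.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^#", lines)
  meta_block <- lines[is_meta]
  body <- lines[!is_meta]
  meta <- list()
  kv <- regmatches(meta_block, regexec("^#\\s*([a-z_]+):\\s*(.*)$", meta_block))
  for (m in kv) if (length(m) == 3L) meta[[m[2]]] <- m[3]

  need <- c("subject_tag", "start_time_epoch", "schedule_family", "schedule_ratio")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("event log header missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(body) == 0L || body[1] != "time_s,kind,tag") {
    stop("event log body must begin with header 'time_s,kind,tag'", call. = FALSE)
  }
  data_lines <- body[-1]
  line_no <- which(!is_meta)[-1]  # file line number of each data row

  n <- length(data_lines)
  if (n == 0L) {
    stop("event log has no event rows", call. = FALSE)
  }
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop(sprintf("malformed event row at line %d: '%s'",
                 line_no[bad[1]], data_lines[bad[1]]), call. = FALSE)
  }
  time_s <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  bad <- which(is.na(time_s))
  if (length(bad)) {
    stop(sprintf("unparseable time at line %d", line_no[bad[1]]), call. = FALSE)
  }
  kind <- vapply(parts, `[`, "", 2L)
  bad <- which(!(kind %in% EVENT_KINDS))
  if (length(bad)) {
    stop(sprintf("unknown event kind '%s' at line %d", kind[bad[1]],
                 line_no[bad[1]]), call. = FALSE)
  }
  tag <- vapply(parts, function(p) if (length(p) >= 3L && nzchar(p[3])) p[3] else NA_character_, "")
  if (is.unsorted(time_s)) {
    bad <- which(diff(time_s) < 0)[1] + 1L
    stop(sprintf("non-monotone event time at line %d", line_no[bad]), call. = FALSE)
  }

  spec <- schedule_spec(
    family = meta$schedule_family,
    ratio = as.integer(meta$schedule_ratio),
    pr_step = as.integer(meta$schedule_pr_step %||% 5L),
    timeout_s = as.numeric(meta$schedule_timeout_s %||% 20),
    cue_s = as.numeric(meta$schedule_cue_s %||% 5),
    session_s = as.numeric(meta$schedule_session_s %||% 3600),
    pr_idle_stop_s = as.numeric(meta$schedule_pr_idle_stop_s %||% 600),
    vr_draws = if (!is.null(meta$schedule_vr_draws))
      as.integer(strsplit(meta$schedule_vr_draws, " ", fixed = TRUE)[[1]])
  )
  session_record(
    subject_tag = meta$subject_tag,
    schedule = spec,
    events = events_frame(time_s, kind, tag),
    start_time = as.POSIXct(as.numeric(meta$start_time_epoch),
                            origin = "1970-01-01", tz = "UTC"),
    seed = if (!is.null(meta$seed)) as.integer(meta$seed)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
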