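#' Construct a position track
#'
#' A position track is the universal currency of the toolkit: timestamped 2-D
#' positions sampled at the nominal detector rate (60 Hz by default).
#' Invalid samples (no occlusion detected at that instant) carry `valid =
#' FALSE` and `NA` coordinates.
#'
#' @param t_ms Numeric vector of timestamps in milliseconds since session
#'   start; must be non-negative and strictly increasing.
#' @param x_mm,y_mm Numeric coordinates in millimetres (frame coordinates,
#'   origin at the frame's lower-left inner corner). `NA` allowed only where
#'   `valid` is `FALSE`.
#' @param valid Logical vector; `FALSE` marks samples with no detection.
#' @return A `data.frame` of class `"ir_track"` with columns `t_ms`, `x_mm`,
#'   `y_mm`, `valid`.
#' @examples
#' position_track(c(0, 16.7, 33.3), c(10, 12, 14), c(20, 20, 20))
#' @export
position_track <- function(t_ms, x_mm = numeric(0), y_mm = numeric(0),
                           valid = NULL) {
  n <- length(t_ms)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(x_mm) != n || length(y_mm) != n || length(valid) != n)
    stop("t_ms, x_mm, y_mm and valid must have equal lengths")
  if (n > 0) {
    if (any(t_ms < 0)) stop("t_ms must be non-negative")
    if (any(diff(t_ms) <= 0))
      stop("t_ms must be strictly increasing (duplicate or non-monotone timestamps)")
    bad <- valid & (!is.finite(x_mm) | !is.finite(y_mm))
    if (any(bad))
      stop("valid samples must have finite coordinates (first offender at t_ms = ",
           t_ms[which(bad)[1]], ")")
  }
  out <- data.frame(t_ms = as.numeric(t_ms), x_mm = as.numeric(x_mm),
                    y_mm = as.numeric(y_mm), valid = as.logical(valid))
  class(out) <- c("ir_track", "data.frame")
  out
}

#' @export
print.ir_track <- function(x, ...) {
  cat(sprintf("<ir_track> %d samples, %.1f s, %d valid (%.1f%%)\n",
              nrow(x), if (nrow(x)) diff(range(x$t_ms)) / 1000 else 0,
              sum(x$valid), if (nrow(x)) 100 * mean(x$valid) else 0))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Read a position log
#'
#' Position logs are comma-separated text with the fixed header
#' `t_ms,x_mm,y_mm,valid`. Invalid samples have empty coordinate fields.
#'
#' @param path Path to the log file.
#' @return An [position_track()] object.
#' @export
read_position_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file (missing header): ", path)
  header <- strsplit(trimws(lines[1]), ",")[[1]]
  if (!identical(header, c("t_ms", "x_mm", "y_mm", "valid")))
    stop("unexpected header in ", path, ": '", lines[1],
         "' (expected 't_ms,x_mm,y_mm,valid')")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0)
    return(position_track(numeric(0), numeric(0), numeric(0), logical(0)))
  parts <- strsplit(body, ",", fixed = TRUE)
  n_fields <- lengths(parts)
  # trailing empty fields are dropped by strsplit; pad invalid rows
  parts <- lapply(parts, function(p) c(p, rep("", 4 - length(p))))
  if (any(n_fields > 4))
    stop("malformed line ", which(n_fields > 4)[1] + 1L, " in ", path,
         ": too many fields")
  m <- do.call(rbind, parts)
  num <- function(s) suppressWarnings(as.numeric(ifelse(s == "", NA, s)))
  t_ms <- num(m[, 1])
  if (anyNA(t_ms))
    stop("malformed line ", which(is.na(t_ms))[1] + 1L, " in ", path,
         ": unparseable t_ms")
  valid <- m[, 4] %in% c("1", "TRUE", "true")
  position_track(t_ms, num(m[, 2]), num(m[, 3]), valid)
}

#' Write a position log
#'
#' @param track An [position_track()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_position_log <- function(track, path) {
  stopifnot(inherits(track, "ir_track"))
  fmt <- function(v) ifelse(is.na(v), "", .num_str(v))
  lines <- c("t_ms,x_mm,y_mm,valid",
             if (nrow(track))
               paste(fmt(track$t_ms), fmt(track$x_mm), fmt(track$y_mm),
                     as.integer(track$valid), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

# shortest decimal representation that round-trips to the same double
.num_str <- function(v) {
  s <- sprintf("%.15g", v)
  long <- suppressWarnings(as.numeric(s)) != v & !is.na(v)
  s[long] <- sprintf("%.17g", v[long])
  s
}

.EVENT_KINDS <- c("trigger", "stim_on", "stim_off", "shock_on", "shock_off",
                  "pulse", "region_entry", "region_exit", "session_start",
                  "session_end", "sync")

#' Construct an event log
#'
#' Ordered, typed events — the synchronization contract with external
#' recorders (photometry, telemetry). Payloads are compact `key=value`
#' strings joined by `;` so that file round trips are bit-exact.
#'
#' @param t_ms Numeric event times (ms), non-negative, non-decreasing.
#' @param kind Character vector of event kinds; one of `trigger`, `stim_on`,
#'   `stim_off`, `shock_on`, `shock_off`, `pulse`, `region_entry`,
#'   `region_exit`, `session_start`, `session_end`, `sync`.
#' @param payload Character vector of `key=value;key=value` payload strings
#'   (may be empty strings).
#' @return A `data.frame` of class `"ir_events"`.
#' @export
event_log <- function(t_ms = numeric(0), kind = character(0),
                      payload = rep("", length(t_ms))) {
  n <- length(t_ms)
  if (length(kind) != n || length(payload) != n)
    stop("t_ms, kind and payload must have equal lengths")
  if (n > 0) {
    if (any(t_ms < 0)) stop("event t_ms must be non-negative")
    if (any(diff(t_ms) < 0))
      stop("events must be ordered by t_ms")
    bad <- !(kind %in% .EVENT_KINDS)
    if (any(bad)) stop("unknown event kind: ", kind[bad][1])
  }
  out <- data.frame(t_ms = as.numeric(t_ms), kind = as.character(kind),
                    payload = as.character(payload))
  class(out) <- c("ir_events", "data.frame")
  out
}

#' @export
print.ir_events <- function(x, ...) {
  cat(sprintf("<ir_events> %d events\n", nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Combine event logs in time order
#'
#' Rows are concatenated and stably sorted by `t_ms`, so simultaneous events
#' keep their argument order.
#' @param ... `ir_events` objects.
#' @return A single merged `ir_events`.
#' @export
merge_events <- function(...) {
  logs <- list(...)
  df <- do.call(rbind, lapply(logs, as.data.frame))
  if (is.null(df) || nrow(df) == 0) return(event_log())
  df <- df[order(df$t_ms), , drop = FALSE]
  event_log(df$t_ms, df$kind, df$payload)
}

#' Read / write event logs
#'
#' Event logs are CSV with header `t_ms,kind,payload`. Writing requires the
#' events to be time-ordered; reading an unordered file is a validation
#' error. Round trips are bit-exact on all three fields.
#'
#' @param events An [event_log()] object.
#' @param path File path.
#' @return `read_event_log` returns an `ir_events`; `write_event_log`
#'   returns `path` invisibly.
#' @export
write_event_log <- function(events, path) {
  stopifnot(inherits(events, "ir_events"))
  lines <- c("t_ms,kind,payload",
             if (nrow(events))
               paste(.num_str(events$t_ms), events$kind,
                     events$payload, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || trimws(lines[1]) != "t_ms,kind,payload")
    stop("unexpected event-log header in ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) return(event_log())
  # payload may itself contain no commas by construction (keys/values use ';')
  m <- regmatches(body, regexec("^([^,]+),([^,]+),(.*)$", body))
  bad <- lengths(m) != 4
  if (any(bad)) stop("malformed line ", which(bad)[1] + 1L, " in ", path)
  m <- do.call(rbind, lapply(m, `[`, -1))
  event_log(as.numeric(m[, 1]), m[, 2], m[, 3])
}

#' Build or parse an event payload string
#'
#' @param ... Named scalar values.
#' @return `payload()` returns a single `key=value;...` string;
#'   `parse_payload()` returns a named character vector.
#' @export
payload <- function(...) {
  kv <- list(...)
  if (!length(kv)) return("")
  vals <- vapply(kv, function(v)
    if (is.numeric(v)) .num_str(v) else as.character(v), "")
  paste(names(kv), vals, sep = "=", collapse = ";")
}

#' @rdname payload
#' @param s A payload string.
#' @export
parse_payload <- function(s) {
  if (!nzchar(s)) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) paste(p[-1], collapse = "="), ""),
                  vapply(parts, `[`, "", 1))
}
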