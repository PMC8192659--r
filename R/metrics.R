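#' Instantaneous speed and acceleration
#'
#' Backward-difference kinematics over the valid samples of a track:
#' `v[i] = |p[i] - p[i-1]| / (t[i] - t[i-1]) * 1000` (mm/s), one value per
#' inter-sample interval, reported at the interval's right endpoint; the
#' first valid sample has `NA` speed. Acceleration is the backward
#' difference of `v` (mm/s^2). No smoothing is applied on the analysis
#' side (the trigger engine applies its own short control-side trailing
#' mean, documented there).
#'
#' @param track An [position_track()] with at least 2 valid samples.
#' @return A `data.frame` with `t_ms`, `v_mms`, `a_mms2`, one row per
#'   valid sample.
#' @examples
#' tr <- position_track((0:3) * 50 / 3, (0:3) * 2.5, rep(0, 4))
#' instantaneous_speed(tr)$v_mms[-1]  # 150 mm/s at every step
#' @export
instantaneous_speed <- function(track) {
  stopifnot(inherits(track, "ir_track"))
  v <- track[track$valid, , drop = FALSE]
  if (nrow(v) < 2)
    stop("insufficient data: instantaneous speed needs >= 2 valid samples")
  dt <- diff(v$t_ms)
  sp <- c(NA_real_, sqrt(diff(v$x_mm)^2 + diff(v$y_mm)^2) / dt * 1000)
  ac <- c(NA_real_, diff(sp) / dt * 1000)
  data.frame(t_ms = v$t_ms, v_mms = sp, a_mms2 = ac)
}

#' Fraction of time spent in a region
#'
#' Sample-and-hold occupancy: each inter-sample interval is attributed to
#' the region membership of its left sample, and the fraction is the sum
#' of in-region intervals over the total track duration. Invalid samples
#' are excluded before the computation.
#'
#' @param track An [position_track()] with at least 2 valid samples.
#' @param region An `ir_region`.
#' @return A fraction in `[0, 1]`.
#' @export
occupancy_fraction <- function(track, region) {
  stopifnot(inherits(track, "ir_track"), inherits(region, "ir_region"))
  v <- track[track$valid, , drop = FALSE]
  if (nrow(v) < 2) stop("occupancy needs >= 2 valid samples")
  inside <- region_contains(region, v$x_mm, v$y_mm)
  dt <- diff(v$t_ms)
  sum(dt[inside[-length(inside)]]) / sum(dt)
}

#' Count entries into a region
#'
#' Convenience wrapper over [region_crossings()]: the number of
#' `region_entry` events (a track starting inside counts one entry).
#' @inheritParams region_crossings
#' @return Integer count.
#' @export
entry_count <- function(track, region, min_dwell_ms = 0) {
  sum(region_crossings(track, region, min_dwell_ms)$kind == "region_entry")
}

#' Summarize a flight to the refuge
#'
#' Computes the escape metrics for a single-trigger trial:
#' \describe{
#'   \item{latency_ms}{first refuge entry after the trigger minus the
#'     trigger time; `NA` if the animal never enters (escape failure is a
#'     valid outcome, not an error).}
#'   \item{hiding_ms}{first refuge exit after that entry minus the entry
#'     time; truncated at the end of the track (and flagged in
#'     `hiding_truncated`) if the session ends while hiding.}
#'   \item{path_mm}{trajectory length from the trigger sample to the entry
#'     sample.}
#'   \item{distance_ratio}{`path_mm` divided by the straight-line distance
#'     from the trigger position to the refuge-entry position. With
#'     `denominator = "entry_point"` (default) the endpoint is the actual
#'     position at the entry sample, which makes `distance_ratio >= 1` a
#'     theorem (triangle inequality); `"doorway_midpoint"` uses the
#'     layout's refuge doorway midpoint instead.}
#'   \item{mean_speed_mms, max_speed_mms}{over the latency period.}
#' }
#'
#' @param track An [position_track()].
#' @param events An [event_log()] containing exactly one `trigger`.
#' @param layout Layout with a `refuge` region.
#' @param denominator Straight-line endpoint convention (see above).
#' @return A one-row `data.frame` of class `"flight_summary"`.
#' @export
flight_summary <- function(track, events, layout,
                           denominator = c("entry_point", "doorway_midpoint")) {
  stopifnot(inherits(track, "ir_track"), inherits(events, "ir_events"),
            inherits(layout, "ir_layout"))
  denominator <- match.arg(denominator)
  trig <- events$t_ms[events$kind == "trigger"]
  if (length(trig) != 1) stop("flight_summary expects exactly one trigger event")
  refuge <- layout$regions$refuge
  if (is.null(refuge)) stop("layout has no refuge region")
  v <- track[track$valid, , drop = FALSE]
  inside <- region_contains(refuge, v$x_mm, v$y_mm)
  i_trig <- which(v$t_ms >= trig)[1]
  if (is.na(i_trig)) stop("trigger time beyond the end of the track")
  trigger_point <- c(x = v$x_mm[i_trig], y = v$y_mm[i_trig])

  # first outside->inside transition at or after the trigger
  i_entry <- NA_integer_
  for (j in seq(i_trig, nrow(v))) {
    if (inside[j] && (j == 1 || !inside[j - 1])) { i_entry <- j; break }
  }
  na_summary <- function() {
    out <- data.frame(latency_ms = NA_real_, hiding_ms = NA_real_,
                      hiding_truncated = NA, path_mm = NA_real_,
                      distance_ratio = NA_real_, mean_speed_mms = NA_real_,
                      max_speed_mms = NA_real_,
                      trigger_x = trigger_point[["x"]],
                      trigger_y = trigger_point[["y"]],
                      entry_x = NA_real_, entry_y = NA_real_)
    class(out) <- c("flight_summary", "data.frame")
    out
  }
  if (is.na(i_entry)) return(na_summary())

  entry_point <- c(x = v$x_mm[i_entry], y = v$y_mm[i_entry])
  seg <- seq(i_trig, i_entry)
  path_mm <- sum(sqrt(diff(v$x_mm[seg])^2 + diff(v$y_mm[seg])^2))
  target <- switch(denominator,
                   entry_point = entry_point,
                   doorway_midpoint = layout$refuge_entry)
  chord <- sqrt(sum((trigger_point - target)^2))
  ratio <- if (chord > 0) path_mm / chord else NA_real_

  # hiding: first exit after the entry, else truncated at track end
  i_exit <- NA_integer_
  if (i_entry < nrow(v)) {
    later <- seq(i_entry + 1L, nrow(v))
    hit <- later[!inside[later]]
    if (length(hit)) i_exit <- hit[1]
  }
  truncated <- is.na(i_exit)
  hide_end <- if (truncated) v$t_ms[nrow(v)] else v$t_ms[i_exit]

  dt <- diff(v$t_ms[seg])
  step <- sqrt(diff(v$x_mm[seg])^2 + diff(v$y_mm[seg])^2)
  sp <- if (length(dt)) step / dt * 1000 else numeric(0)
  out <- data.frame(latency_ms = v$t_ms[i_entry] - trig,
                    hiding_ms = hide_end - v$t_ms[i_entry],
                    hiding_truncated = truncated,
                    path_mm = path_mm, distance_ratio = ratio,
                    mean_speed_mms = if (length(sp)) mean(sp) else NA_real_,
                    max_speed_mms = if (length(sp)) max(sp) else NA_real_,
                    trigger_x = trigger_point[["x"]],
                    trigger_y = trigger_point[["y"]],
                    entry_x = entry_point[["x"]], entry_y = entry_point[["y"]])
  class(out) <- c("flight_summary", "data.frame")
  out
}

#' Event-aligned average of time series
#'
#' Aligns a scalar time series (e.g. a speed series) to a set of event
#' onsets, resamples each trial onto a common grid at the series' native
#' rate, and averages pointwise. Trials whose window is not fully covered
#' by the series are dropped and reported.
#'
#' @param series A `data.frame` with `t_ms` and a value column (the second
#'   column is used), or a list of such data frames (one per subject; each
#'   onset is looked up in every series that covers it).
#' @param onsets Numeric vector of event times (ms).
#' @param window Length-2 numeric `c(pre_ms, post_ms)`, both positive;
#'   the window spans `[onset - pre_ms, onset + post_ms]`.
#' @return A list with `t_ms` (grid, 0 = onset), `mean`, `sd`, `sem`, `n`
#'   (trials per timepoint, constant), `trials` (trial x time matrix), and
#'   `dropped` (number of unusable trials).
#' @export
event_aligned_average <- function(series, onsets, window) {
  if (is.data.frame(series)) series <- list(series)
  stopifnot(length(window) == 2, all(window > 0), length(onsets) >= 1)
  dts <- unlist(lapply(series, function(s) diff(s$t_ms)))
  dt <- stats::median(dts)
  grid <- seq(-window[1], window[2], by = dt)
  rows <- list(); dropped <- 0L
  for (s in series) {
    val <- s[[2]]
    ok <- !is.na(val)
    for (on in onsets) {
      tt <- on + grid
      if (min(tt) < min(s$t_ms[ok]) || max(tt) > max(s$t_ms[ok])) {
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        stats::approx(s$t_ms[ok], val[ok], xout = tt)$y
    }
  }
  if (!length(rows))
    stop("no usable trials: all ", dropped, " onset(s) lack full window coverage")
  m <- do.call(rbind, rows)
  n <- nrow(m)
  list(t_ms = grid,
       mean = colMeans(m),
       sd = apply(m, 2, stats::sd),
       sem = apply(m, 2, stats::sd) / sqrt(n),
       n = rep(n, length(grid)),
       trials = m, dropped = dropped)
}

#' Per-session metrics table
#'
#' The `analyze` summary: occupancy fraction and entry count for every
#' region of the layout, plus the flight summary columns when the event
#' log contains exactly one trigger.
#'
#' @param track An [position_track()].
#' @param events An [event_log()] (may be empty).
#' @param layout An [make_layout()] layout.
#' @return A `data.frame` with one row per region (`region`, `occupancy`,
#'   `entries`), with the flight summary attached as the
#'   `"flight"` attribute when available.
#' @export
session_metrics <- function(track, events, layout) {
  regs <- layout$regions
  tab <- data.frame(
    region = names(regs),
    occupancy = vapply(regs, function(r) occupancy_fraction(track, r), 0),
    entries = vapply(regs, function(r) entry_count(track, r), 0L),
    row.names = NULL)
  if (sum(events$kind == "trigger") == 1 && !is.null(regs$refuge))
    attr(tab, "flight") <- flight_summary(track, events, layout)
  tab
}
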