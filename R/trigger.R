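#' Closed-loop trigger configuration
#'
#' Encodes the predefined conditions under which a stimulus fires: the
#' animal must be inside the trigger zone, moving slower than
#' `speed_max_mms`, after the habituation period, at least `refractory_ms`
#' after the previous trigger, with fewer than `max_triggers` already
#' fired. Paradigm presets carry the protocol constants:
#' \describe{
#'   \item{looming}{zone Ø250 mm, speed < 150 mm/s, habituation 300 s,
#'     1 trigger per session, session ends 120 s after the trigger,
#'     session cap 900 s.}
#'   \item{footshock}{same zone/speed/habituation; the 3-min lockout is
#'     enforced by the shock controller relative to the end of each 6-s
#'     shock window, so `refractory_ms` is 0 here and triggers are
#'     uncapped within the session.}
#'   \item{opto}{same zone/speed/habituation; at most 5 triggers within
#'     the 30-min active window that starts when habituation ends, and at
#'     least 180 s between triggers.}
#' }
#'
#' @param paradigm Preset name: `"looming"`, `"footshock"`, or `"opto"`.
#' @param ... Overrides of any preset field: `zone`, `speed_max_mms`,
#'   `habituation_ms`, `refractory_ms`, `max_triggers`,
#'   `session_end_after_trigger_ms`, `session_max_ms`, `speed_window`.
#' @return An object of class `"trigger_config"`.
#' @export
trigger_config <- function(paradigm = c("looming", "footshock", "opto"), ...) {
  paradigm <- match.arg(paradigm)
  base <- switch(paradigm,
    looming = list(zone = "trigger_zone", speed_max_mms = 150,
                   habituation_ms = 300e3, refractory_ms = 180e3,
                   max_triggers = 1, session_end_after_trigger_ms = 120e3,
                   session_max_ms = 900e3),
    footshock = list(zone = "trigger_zone", speed_max_mms = 150,
                     habituation_ms = 300e3, refractory_ms = 0,
                     max_triggers = Inf, session_end_after_trigger_ms = NA,
                     session_max_ms = 900e3),
    opto = list(zone = "trigger_zone", speed_max_mms = 150,
                habituation_ms = 300e3, refractory_ms = 180e3,
                max_triggers = 5, session_end_after_trigger_ms = NA,
                session_max_ms = 300e3 + 1800e3))
  cfg <- utils::modifyList(c(base, list(speed_window = 3L, paradigm = paradigm)),
                           list(...))
  durs <- c(cfg$habituation_ms, cfg$refractory_ms,
            cfg$session_end_after_trigger_ms, cfg$session_max_ms)
  if (any(durs < 0, na.rm = TRUE)) stop("durations must be >= 0")
  if (!(cfg$speed_max_mms > 0)) stop("speed_max_mms must be positive")
  structure(cfg, class = "trigger_config")
}

#' @export
print.trigger_config <- function(x, ...) {
  cat(sprintf(paste0("<trigger_config> %s: zone=%s, speed < %g mm/s, ",
                     "habituation %g s, refractory %g s, cap %s\n"),
              x$paradigm, x$zone, x$speed_max_mms, x$habituation_ms / 1e3,
              x$refractory_ms / 1e3, format(x$max_triggers)))
  invisible(x)
}

# Trailing-mean control-side speed at each valid sample. Raw one-sample
# speed at 2 mm pitch quantization can alias above threshold, so the
# trigger condition uses a short trailing mean (default 3 samples = 50 ms
# at 60 Hz). The first valid sample has no defined speed (NA).
.control_speed <- function(t_ms, x_mm, y_mm, window = 3L) {
  n <- length(t_ms)
  v <- rep(NA_real_, n)
  if (n >= 2) {
    dt <- diff(t_ms)
    v[-1] <- sqrt(diff(x_mm)^2 + diff(y_mm)^2) / dt * 1000
  }
  sm <- rep(NA_real_, n)
  for (i in 2:max(2, n)) {
    lo <- max(2, i - window + 1L)
    sm[i] <- mean(v[lo:i])
  }
  if (n < 2) sm <- rep(NA_real_, n)
  sm
}

#' Evaluate the closed-loop trigger rules on a track
#'
#' Pure batch evaluation of the real-time loop, in sample order with no
#' look-ahead: a `trigger` event is emitted at the first sample where all
#' conditions hold (post-habituation, inside the zone, trailing-mean speed
#' strictly below threshold, refractory elapsed, cap not reached). A
#' `session_end` event is emitted at
#' `min(session_max_ms, first_trigger + session_end_after_trigger_ms)`
#' (whichever components are configured); no triggers are emitted after
#' session end. Identical inputs produce bit-identical event logs.
#'
#' @param track An [position_track()] at the nominal detector rate.
#' @param layout An [make_layout()] layout containing `cfg$zone`.
#' @param cfg A [trigger_config()].
#' @return An [event_log()] with `trigger` events (payload `index`, `speed`)
#'   and a `session_end` event when an end rule applies.
#' @export
evaluate_triggers <- function(track, layout, cfg) {
  stopifnot(inherits(track, "ir_track"), inherits(layout, "ir_layout"),
            inherits(cfg, "trigger_config"))
  zone <- layout$regions[[cfg$zone]]
  if (is.null(zone)) stop("trigger zone '", cfg$zone, "' not found in layout")
  v <- track[track$valid, , drop = FALSE]
  ev_t <- numeric(0); ev_k <- character(0); ev_p <- character(0)
  end_t <- if (is.finite(cfg$session_max_ms)) cfg$session_max_ms else NA_real_
  if (nrow(v)) {
    speed <- .control_speed(v$t_ms, v$x_mm, v$y_mm, cfg$speed_window)
    inzone <- region_contains(zone, v$x_mm, v$y_mm)
    eligible <- which(v$t_ms >= cfg$habituation_ms & inzone &
                      !is.na(speed) & speed < cfg$speed_max_mms)
    trig_t <- numeric(length(eligible))
    trig_sp <- numeric(length(eligible))
    last_trig <- -Inf
    n_trig <- 0L
    for (i in eligible) {
      t <- v$t_ms[i]
      if (!is.na(end_t) && t > end_t) break
      if (t - last_trig < cfg$refractory_ms) next
      if (n_trig >= cfg$max_triggers) break
      n_trig <- n_trig + 1L
      last_trig <- t
      trig_t[n_trig] <- t
      trig_sp[n_trig] <- speed[i]
      if (n_trig == 1L && !is.na(cfg$session_end_after_trigger_ms))
        end_t <- min(end_t, t + cfg$session_end_after_trigger_ms, na.rm = TRUE)
    }
    if (n_trig > 0L) {
      ev_t <- trig_t[seq_len(n_trig)]
      ev_k <- rep("trigger", n_trig)
      ev_p <- vapply(seq_len(n_trig), function(k)
        payload(index = k, speed = trig_sp[k]), "")
    }
  }
  if (!is.na(end_t)) {
    ev_t <- c(ev_t, end_t); ev_k <- c(ev_k, "session_end"); ev_p <- c(ev_p, "")
  }
  event_log(ev_t, ev_k, ev_p)
}

#' Looming stimulus specification and timeline
#'
#' The looming stimulus is an overhead dark disk whose visual angle expands
#' linearly from `theta_start_deg` to `theta_end_deg` over `expand_ms`,
#' holds for `hold_ms`, disappears, and repeats `repeats` times with
#' `gap_ms` between repeats. For a monitor `monitor_height_mm` above the
#' floor, the on-screen disk diameter at angle theta is
#' `2 * monitor_height_mm * tan(theta / 2)`.
#'
#' @param theta_start_deg,theta_end_deg Visual angle endpoints (degrees).
#' @param expand_ms,hold_ms,gap_ms Phase durations (ms).
#' @param repeats Number of repeats.
#' @param monitor_height_mm Monitor elevation above the floor (mm).
#' @return An object of class `"looming_spec"`.
#' @export
looming_spec <- function(theta_start_deg = 2, theta_end_deg = 40,
                         expand_ms = 300, hold_ms = 50, repeats = 15,
                         gap_ms = 30, monitor_height_mm = 460) {
  stopifnot(theta_start_deg < theta_end_deg, expand_ms > 0, hold_ms > 0,
            gap_ms > 0, repeats >= 1, monitor_height_mm > 0)
  structure(list(theta_start_deg = theta_start_deg,
                 theta_end_deg = theta_end_deg, expand_ms = expand_ms,
                 hold_ms = hold_ms, repeats = repeats, gap_ms = gap_ms,
                 monitor_height_mm = monitor_height_mm),
            class = "looming_spec")
}

#' @rdname looming_spec
#' @param spec A `looming_spec`.
#' @param t0 Stimulus onset time (ms).
#' @return `looming_timeline` returns a list: `events` (an [event_log()]
#'   with `stim_on` at `t0` and `stim_off` at the end of the last hold),
#'   `segments` (per-repeat expansion/hold intervals), and functions
#'   `theta_deg(t_ms)` and `diameter_mm(t_ms)` giving the commanded visual
#'   angle and on-screen diameter (`NA` outside expansion/hold phases).
#' @examples
#' tl <- looming_timeline(looming_spec(), 0)
#' tl$events$t_ms[2]          # 5670: 15*(300+50) + 14*30
#' tl$theta_deg(150)          # 21: halfway through the first expansion
#' @export
looming_timeline <- function(spec = looming_spec(), t0 = 0) {
  stopifnot(inherits(spec, "looming_spec"))
  period <- spec$expand_ms + spec$hold_ms + spec$gap_ms
  starts <- t0 + (seq_len(spec$repeats) - 1) * period
  segments <- data.frame(
    repeat_idx = seq_len(spec$repeats),
    expand_start = starts,
    hold_start = starts + spec$expand_ms,
    hold_end = starts + spec$expand_ms + spec$hold_ms)
  t_off <- segments$hold_end[spec$repeats]
  theta_fun <- function(t_ms) {
    vapply(t_ms, function(t) {
      k <- findInterval(t, segments$expand_start)
      if (k < 1 || t > segments$hold_end[k]) return(NA_real_)
      if (t <= segments$hold_start[k]) {
        frac <- (t - segments$expand_start[k]) / spec$expand_ms
        spec$theta_start_deg + frac * (spec$theta_end_deg - spec$theta_start_deg)
      } else spec$theta_end_deg
    }, 0)
  }
  diam_fun <- function(t_ms) {
    th <- theta_fun(t_ms)
    2 * spec$monitor_height_mm * tan(th / 2 * pi / 180)
  }
  list(events = event_log(c(t0, t_off), c("stim_on", "stim_off"),
                          c(payload(stimulus = "looming"), "")),
       segments = segments, theta_deg = theta_fun, diameter_mm = diam_fun,
       duration_ms = t_off - t0)
}

#' Foot-shock specification
#'
#' Shock episode rules: the shock starts at the trigger, stops as soon as
#' the animal enters the refuge, restarts if it exits the refuge within
#' `rearm_window_ms` of the initial trigger, stops unconditionally
#' `max_on_ms` after the trigger, and the trigger is then inactive for
#' `lockout_ms`.
#'
#' @param current_mA Shock current (mA), carried as event payload.
#' @param max_on_ms Unconditional stop, ms after the trigger (default 6 s).
#' @param rearm_window_ms Re-arm window anchored at the trigger (default 6 s).
#' @param lockout_ms Trigger lockout after the shock window closes
#'   (default 180 s).
#' @return An object of class `"shock_spec"`.
#' @export
shock_spec <- function(current_mA = 0.5, max_on_ms = 6e3,
                       rearm_window_ms = 6e3, lockout_ms = 180e3) {
  stopifnot(current_mA > 0, max_on_ms > 0, rearm_window_ms > 0, lockout_ms > 0)
  structure(list(current_mA = current_mA, max_on_ms = max_on_ms,
                 rearm_window_ms = rearm_window_ms, lockout_ms = lockout_ms),
            class = "shock_spec")
}

#' Run the foot-shock state machine over candidate triggers
#'
#' Applies the episode rules of [shock_spec()] to each accepted trigger.
#' Candidate triggers falling inside a previous episode's window or lockout
#' are discarded (the trigger is "not active"). Refuge entries and exits
#' are taken from the track's valid samples.
#'
#' @param track An [position_track()].
#' @param layout Layout containing a `refuge` region.
#' @param triggers An [event_log()] of candidate `trigger` events (e.g.
#'   from [evaluate_triggers()] with the `footshock` preset).
#' @param spec A [shock_spec()].
#' @return An [event_log()] of accepted `trigger`, `shock_on` and
#'   `shock_off` events; shock events carry `current_mA` payloads.
#' @export
shock_controller <- function(track, layout, triggers, spec = shock_spec()) {
  stopifnot(inherits(track, "ir_track"), inherits(layout, "ir_layout"),
            inherits(triggers, "ir_events"), inherits(spec, "shock_spec"))
  refuge <- layout$regions$refuge
  if (is.null(refuge)) stop("layout has no refuge region")
  v <- track[track$valid, , drop = FALSE]
  inside <- if (nrow(v)) region_contains(refuge, v$x_mm, v$y_mm) else logical(0)
  cand <- triggers$t_ms[triggers$kind == "trigger"]
  ev_t <- numeric(0); ev_k <- character(0); ev_p <- character(0)
  emit <- function(t, k, p = "") {
    ev_t <<- c(ev_t, t); ev_k <<- c(ev_k, k); ev_p <<- c(ev_p, p)
  }
  pay <- payload(current_mA = spec$current_mA)
  active_from <- -Inf
  for (T in cand) {
    if (T < active_from) next
    emit(T, "trigger", payload(stimulus = "footshock"))
    t_stop <- T + spec$max_on_ms
    # walk refuge crossings strictly after T, within the shock window
    state_on <- TRUE
    emit(T, "shock_on", pay)
    i <- which(v$t_ms >= T)[1]
    if (!is.na(i) && length(inside) && inside[i]) {
      # triggered while already in the refuge: degenerate immediate stop
      emit(T, "shock_off", pay)
      state_on <- FALSE
    }
    if (!is.na(i)) {
      prev_in <- if (length(inside)) inside[i] else FALSE
      for (j in seq(i, nrow(v))) {
        t <- v$t_ms[j]
        if (t >= t_stop) break
        if (inside[j] && !prev_in && state_on) {        # refuge entry
          emit(t, "shock_off", pay); state_on <- FALSE
        } else if (!inside[j] && prev_in && !state_on &&
                   t < T + spec$rearm_window_ms) {      # exit within re-arm window
          emit(t, "shock_on", pay); state_on <- TRUE
        }
        prev_in <- inside[j]
      }
    }
    if (state_on) emit(t_stop, "shock_off", pay)
    active_from <- t_stop + spec$lockout_ms
  }
  event_log(ev_t, ev_k, ev_p)
}

#' Optogenetic pulse-train specification and generator
#'
#' A laser epoch of `epoch_ms` at `rate_hz` with `pulse_ms` pulses
#' (defaults: 2.5 s at 20 Hz, 5 ms pulses).
#'
#' @param epoch_ms Epoch duration (ms).
#' @param rate_hz Pulse rate (Hz).
#' @param pulse_ms Pulse duration (ms); must be shorter than the pulse
#'   period `1000 / rate_hz`.
#' @return An object of class `"opto_spec"`.
#' @export
opto_spec <- function(epoch_ms = 2500, rate_hz = 20, pulse_ms = 5) {
  stopifnot(epoch_ms > 0, rate_hz > 0)
  if (!(pulse_ms < 1000 / rate_hz))
    stop("pulse_ms must be shorter than the pulse period (pulses would overlap)")
  structure(list(epoch_ms = epoch_ms, rate_hz = rate_hz, pulse_ms = pulse_ms),
            class = "opto_spec")
}

#' @rdname opto_spec
#' @param spec An `opto_spec`.
#' @param t0 Epoch onset (ms).
#' @return `opto_train` returns an [event_log()]: `stim_on` at `t0`,
#'   `pulse` events at `t0 + k * 1000 / rate_hz` for
#'   `k = 0 .. floor(epoch_ms * rate_hz / 1000) - 1` (payload
#'   `duration_ms`), and `stim_off` at `t0 + epoch_ms`.
#' @examples
#' ev <- opto_train(opto_spec(), 0)
#' sum(ev$kind == "pulse")  # 50
#' @export
opto_train <- function(spec = opto_spec(), t0 = 0) {
  stopifnot(inherits(spec, "opto_spec"))
  n_pulse <- floor(spec$epoch_ms * spec$rate_hz / 1000)
  onsets <- t0 + (seq_len(n_pulse) - 1) * (1000 / spec$rate_hz)
  event_log(c(t0, onsets, t0 + spec$epoch_ms),
            c("stim_on", rep("pulse", n_pulse), "stim_off"),
            c(payload(stimulus = "opto"),
              rep(payload(duration_ms = spec$pulse_ms), n_pulse), ""))
}
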