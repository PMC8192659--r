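#' Mouse agent parameters
#'
#' The agent's exploratory velocity follows a mean-reverting
#' (Ornstein-Uhlenbeck) process — the simplest stationary model producing
#' mouse-like meandering — and its response to a stimulus is a straight
#' dash to the refuge doorway at a commanded speed after a reaction
#' latency, followed by a dwell inside the refuge.
#'
#' @param body_mm Footprint size (mm); the agent casts a square shadow of
#'   this side when run through the beam-grid simulator.
#' @param explore_speed_mms Mean exploratory speed (mm/s). The stationary
#'   speed of the 2-D OU process is Rayleigh; the per-axis diffusion scale
#'   is set so the mean speed matches this value.
#' @param relax_ms Velocity relaxation time of the OU process (ms).
#' @param noise Dimensionless multiplier on the stationary velocity scale
#'   (1 = full exploration; 0 = deterministic, a static agent when the
#'   initial velocity is zero).
#' @param flight_speed_mms Commanded escape speed (mm/s); must exceed
#'   `explore_speed_mms`.
#' @param react_ms Latency from stimulus onset to flight onset (ms).
#' @param hide_ms Refuge dwell after a flight (ms).
#' @param flight_noise_mm Lateral waypoint jitter during flight (mm per
#'   step, default 0 = perfectly straight dash).
#' @return An object of class `"mouse_sim_params"`.
#' @export
mouse_sim_params <- function(body_mm = 40, explore_speed_mms = 80,
                             relax_ms = 500, noise = 1,
                             flight_speed_mms = 600, react_ms = 100,
                             hide_ms = 20e3, flight_noise_mm = 0) {
  stopifnot(body_mm > 0, explore_speed_mms > 0, relax_ms > 0, noise >= 0,
            flight_speed_mms > explore_speed_mms, react_ms >= 0, hide_ms >= 0,
            flight_noise_mm >= 0)
  structure(list(body_mm = body_mm, explore_speed_mms = explore_speed_mms,
                 relax_ms = relax_ms, noise = noise,
                 flight_speed_mms = flight_speed_mms, react_ms = react_ms,
                 hide_ms = hide_ms, flight_noise_mm = flight_noise_mm),
            class = "mouse_sim_params")
}

.reflect_disk <- function(p, v, c0, r) {
  d <- sqrt(sum((p - c0)^2))
  if (d > r && d > 0) {
    n <- (p - c0) / d
    p <- c0 + (2 * r - d) * n
    v <- v - 2 * sum(v * n) * n
  }
  list(p = p, v = v)
}

#' Simulate an exploratory trajectory
#'
#' Mean-reverting-velocity random walk at the detector rate, reflected at
#' the open-area boundary. Deterministic under a fixed seed.
#'
#' @param params A [mouse_sim_params()].
#' @param layout A layout with an `open_area` region (disk).
#' @param duration_ms Session duration (ms); at least 2 samples.
#' @param rate_hz Sampling rate (Hz), default 60.
#' @param seed Integer RNG seed.
#' @return An [position_track()].
#' @export
explore_trajectory <- function(params, layout, duration_ms, rate_hz = 60,
                               seed = 1) {
  stopifnot(inherits(params, "mouse_sim_params"), inherits(layout, "ir_layout"))
  open_area <- layout$regions$open_area
  if (is.null(open_area) || open_area$type != "disk")
    stop("layout needs a disk open_area region")
  dt <- 1000 / rate_hz
  n <- floor(duration_ms / dt) + 1
  if (n < 2) stop("duration shorter than 2 samples")
  set.seed(seed)
  c0 <- c(open_area$cx, open_area$cy)
  r_in <- open_area$r - params$body_mm / 2
  a <- exp(-dt / params$relax_ms)
  sig <- params$noise * params$explore_speed_mms / sqrt(pi / 2)
  kick <- sig * sqrt(1 - a^2)
  p <- c0
  v <- c(0, 0)
  xs <- ys <- numeric(n)
  xs[1] <- p[1]; ys[1] <- p[2]
  for (i in 2:n) {
    v <- v * a + kick * stats::rnorm(2)
    p <- p + v * dt / 1000
    rf <- .reflect_disk(p, v, c0, r_in)
    p <- rf$p; v <- rf$v
    xs[i] <- p[1]; ys[i] <- p[2]
  }
  position_track((seq_len(n) - 1) * dt, xs, ys)
}

#' Run a closed-loop synthetic session
#'
#' The agent explores; the trigger rules of `cfg` are evaluated online at
#' each sample (the same conditions as [evaluate_triggers()], with no
#' look-ahead); on a trigger the agent keeps exploring for `react_ms`,
#' then dashes straight to the refuge doorway and on to the refuge center
#' at the commanded flight speed, dwells `hide_ms`, walks back to the
#' arena center, and resumes exploring. The session ends at
#' `min(session_max_ms, first trigger + session_end_after_trigger_ms)`
#' (whichever components are configured) or `duration_ms`.
#'
#' @param params A [mouse_sim_params()].
#' @param layout A looming-family layout (`open_area`, `trigger_zone`,
#'   `refuge`).
#' @param cfg A [trigger_config()].
#' @param stimulus Optional stimulus spec ([looming_spec()], [shock_spec()]
#'   or [opto_spec()]); its events are merged into the session event log
#'   at each trigger. `NULL` = trigger events only (or a negative-control
#'   session when `triggers_active = FALSE`).
#' @param duration_ms Maximum session duration (ms).
#' @param rate_hz Sampling rate (Hz), default 60.
#' @param seed Integer RNG seed.
#' @param triggers_active If `FALSE`, the trigger engine is disarmed (the
#'   negative-control protocol): the agent simply explores.
#' @return A list of class `"synthetic_session"`: `track`, `events`
#'   (an [event_log()]), and `ground_truth` (`data.frame` of trigger
#'   times, flight onsets, trigger positions and commanded speed).
#' @export
closed_loop_session <- function(params, layout, cfg, stimulus = NULL,
                                duration_ms = 900e3, rate_hz = 60, seed = 1,
                                triggers_active = TRUE) {
  stopifnot(inherits(params, "mouse_sim_params"), inherits(layout, "ir_layout"),
            inherits(cfg, "trigger_config"))
  zone <- layout$regions[[cfg$zone]]
  if (is.null(zone)) stop("trigger zone '", cfg$zone, "' not found in layout")
  open_area <- layout$regions$open_area
  refuge <- layout$regions$refuge
  entry <- layout$refuge_entry
  hide_pt <- c(mean(c(refuge$x0, refuge$x1)), mean(c(refuge$y0, refuge$y1)))
  center <- layout$arena_center
  dt <- 1000 / rate_hz
  set.seed(seed)
  c0 <- c(open_area$cx, open_area$cy)
  r_in <- open_area$r - params$body_mm / 2
  a <- exp(-dt / params$relax_ms)
  sig <- params$noise * params$explore_speed_mms / sqrt(pi / 2)
  kick <- sig * sqrt(1 - a^2)

  end_t <- if (is.finite(cfg$session_max_ms))
    min(cfg$session_max_ms, duration_ms) else duration_ms
  n_max <- floor(duration_ms / dt) + 1
  xs <- ys <- ts <- numeric(n_max)
  p <- c0; v <- c(0, 0)
  xs[1] <- p[1]; ys[1] <- p[2]; ts[1] <- 0
  raw_v <- rep(NA_real_, n_max)          # instantaneous speed per sample
  state <- "explore"
  state_until <- Inf
  target <- NULL
  last_trig <- -Inf; n_trig <- 0L
  trig_t <- numeric(0); trig_x <- numeric(0); trig_y <- numeric(0)
  flight_on <- numeric(0)
  i <- 1L
  while (ts[i] + dt <= end_t + 1e-9 && i < n_max) {
    i <- i + 1L
    t <- ts[i - 1] + dt
    # -- agent motion
    if (state == "explore" ||
        (state == "react" && t < state_until)) {
      v <- v * a + kick * stats::rnorm(2)
      p <- p + v * dt / 1000
      rf <- .reflect_disk(p, v, c0, r_in)
      p <- rf$p; v <- rf$v
    } else if (state == "react") {
      state <- "flight"; target <- entry
      flight_on <- c(flight_on, t)
    }
    if (state %in% c("flight", "return")) {
      speed_cmd <- if (state == "flight") params$flight_speed_mms
                   else params$explore_speed_mms
      step <- speed_cmd * dt / 1000
      d <- sqrt(sum((target - p)^2))
      if (d <= step) {
        p <- target
        if (state == "flight" && !isTRUE(all.equal(target, hide_pt))) {
          target <- hide_pt              # through the doorway to the hide point
        } else if (state == "flight") {
          state <- "hide"; state_until <- t + params$hide_ms
        } else {
          state <- "explore"; v <- c(0, 0)
        }
      } else {
        dir <- (target - p) / d
        if (params$flight_noise_mm > 0 && state == "flight") {
          perp <- c(-dir[2], dir[1])
          p <- p + perp * stats::rnorm(1, 0, params$flight_noise_mm)
        }
        p <- p + dir * step
      }
      v <- c(0, 0)
    } else if (state == "hide" && t >= state_until) {
      state <- "return"; target <- center
    }
    xs[i] <- p[1]; ys[i] <- p[2]; ts[i] <- t
    raw_v[i] <- sqrt((xs[i] - xs[i - 1])^2 + (ys[i] - ys[i - 1])^2) / dt * 1000
    # -- online trigger evaluation (same gates as evaluate_triggers)
    if (triggers_active && state %in% c("explore", "react")) {
      lo <- max(2L, i - cfg$speed_window + 1L)
      sm <- mean(raw_v[lo:i])
      if (t >= cfg$habituation_ms &&
          region_contains(zone, p[1], p[2]) &&
          !is.na(sm) && sm < cfg$speed_max_mms &&
          t - last_trig >= cfg$refractory_ms &&
          n_trig < cfg$max_triggers &&
          state == "explore") {
        n_trig <- n_trig + 1L; last_trig <- t
        trig_t <- c(trig_t, t); trig_x <- c(trig_x, p[1]); trig_y <- c(trig_y, p[2])
        state <- "react"; state_until <- t + params$react_ms
        if (n_trig == 1L && !is.na(cfg$session_end_after_trigger_ms))
          end_t <- min(end_t, t + cfg$session_end_after_trigger_ms)
      }
    }
  }
  track <- position_track(ts[1:i], xs[1:i], ys[1:i])
  ev <- event_log(c(0, trig_t, end_t),
                  c("session_start", rep("trigger", length(trig_t)), "session_end"),
                  c("", vapply(seq_along(trig_t), function(k)
                      payload(index = k), ""), ""))
  if (!is.null(stimulus) && length(trig_t)) {
    stim_ev <- lapply(trig_t, function(t0) {
      if (inherits(stimulus, "looming_spec")) looming_timeline(stimulus, t0)$events
      else if (inherits(stimulus, "opto_spec")) opto_train(stimulus, t0)
      else if (inherits(stimulus, "shock_spec"))
        shock_controller(track, layout,
                         event_log(t0, "trigger", ""), stimulus)
      else stop("unsupported stimulus spec")
    })
    ev <- do.call(merge_events, c(list(ev), stim_ev))
  }
  gt <- data.frame(trigger_t_ms = trig_t,
                   flight_onset_ms = if (length(flight_on)) flight_on[seq_along(trig_t)] else numeric(0),
                   trigger_x = trig_x, trigger_y = trig_y,
                   commanded_speed_mms = rep(params$flight_speed_mms, length(trig_t)))
  structure(list(track = track, events = ev, ground_truth = gt,
                 layout = layout, params = params, cfg = cfg),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %s: %d samples, %d trigger(s)\n",
              x$layout$name, nrow(x$track), nrow(x$ground_truth)))
  invisible(x)
}

#' Generate the cube displacement-accuracy protocol
#'
#' Builds the occlusion fixtures of the spatial-accuracy evaluation: a
#' cube placed at each test position, then displaced by each magnitude,
#' with every manipulation repeated. Defaults follow the protocol:
#' 20 positions (a 5 x 4 checkerboard-pitch lattice around the frame
#' center, ordered by distance to the center), displacements of 1, 2, 5
#' and 10 mm along +x, 5 repeats. Placement is exact (repeats are
#' identical) unless `jitter_mm > 0` adds placement noise; ground truth
#' always records the actual cube centers.
#'
#' @param grid A [beam_grid()].
#' @param positions Optional 2-column matrix of base positions (mm).
#' @param displacements_mm Displacement magnitudes (mm).
#' @param repeats Repeats per manipulation.
#' @param cube_mm Cube side (mm), default 40.
#' @param jitter_mm SD of placement jitter (mm), default 0.
#' @param seed RNG seed (used only when `jitter_mm > 0`).
#' @return A list of class `"cube_protocol"`: `truth` (one row per
#'   (position, displacement, repeat): true base and displaced centers)
#'   and `snapshots` (parallel list of `list(base, displaced)` occlusion
#'   snapshots).
#' @export
cube_protocol <- function(grid, positions = NULL,
                          displacements_mm = c(1, 2, 5, 10), repeats = 5,
                          cube_mm = 40, jitter_mm = 0, seed = 1) {
  stopifnot(inherits(grid, "beam_grid"))
  if (is.null(positions)) {
    cx <- grid$width_mm / 2; cy <- grid$height_mm / 2
    pitch <- 40
    pts <- expand.grid(x = cx + pitch * c(-8, -4, 0, 4, 8),
                       y = cy + pitch * c(-3, -1, 1, 3))
    pts <- pts[order((pts$x - cx)^2 + (pts$y - cy)^2), ]
    positions <- as.matrix(pts)
  }
  h <- cube_mm / 2
  maxd <- max(displacements_mm)
  out_of_frame <- positions[, 1] - h < 0 |
    positions[, 1] + h + maxd > grid$width_mm |
    positions[, 2] - h < 0 | positions[, 2] + h > grid$height_mm
  if (any(out_of_frame))
    stop("displaced cube leaves the frame at position ",
         which(out_of_frame)[1])
  set.seed(seed)
  rows <- list(); snaps <- list()
  k <- 0L
  for (p in seq_len(nrow(positions))) {
    for (d in displacements_mm) {
      for (rep_i in seq_len(repeats)) {
        jit <- if (jitter_mm > 0) stats::rnorm(4, 0, jitter_mm) else rep(0, 4)
        base <- positions[p, ] + jit[1:2]
        disp <- positions[p, ] + c(d, 0) + jit[3:4]
        k <- k + 1L
        rows[[k]] <- data.frame(position = p, displacement_mm = d,
                                repeat_idx = rep_i,
                                base_x = base[1], base_y = base[2],
                                disp_x = disp[1], disp_y = disp[2])
        snaps[[k]] <- list(
          base = occlude(occupant_square(base[1], base[2], cube_mm), grid),
          displaced = occlude(occupant_square(disp[1], disp[2], cube_mm), grid))
      }
    }
  }
  structure(list(truth = do.call(rbind, rows), snapshots = snaps,
                 grid = grid, positions = positions),
            class = "cube_protocol")
}

#' Decode a cube protocol and report accuracy
#'
#' Runs every fixture of a [cube_protocol()] through [decode_position()]
#' and assembles the [accuracy_report()] inputs: decoded base positions
#' per (position, repeat) and measured displacement magnitudes per
#' (position, displacement, repeat).
#'
#' @param protocol A `cube_protocol`.
#' @return A list: `observed` (decoded base positions), `reference` (true
#'   base positions), `displacements` (true vs measured magnitudes), and
#'   `report` (the [accuracy_report()]).
#' @export
decode_cube_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "cube_protocol"))
  tr <- protocol$truth
  dec <- lapply(protocol$snapshots, function(s) {
    b <- decode_position(s$base, protocol$grid)
    d <- decode_position(s$displaced, protocol$grid)
    c(b$x_mm, b$y_mm, d$x_mm, d$y_mm)
  })
  dec <- do.call(rbind, dec)
  observed <- data.frame(position = tr$position, repeat_idx = tr$repeat_idx,
                         x = dec[, 1], y = dec[, 2])
  reference <- data.frame(position = seq_len(nrow(protocol$positions)),
                          x = protocol$positions[, 1],
                          y = protocol$positions[, 2])
  displacements <- data.frame(
    position = tr$position, displacement_mm = tr$displacement_mm,
    repeat_idx = tr$repeat_idx,
    measured_mm = sqrt((dec[, 3] - dec[, 1])^2 + (dec[, 4] - dec[, 2])^2))
  # one observed base row per (position, repeat): take displacement == first
  first_d <- tr$displacement_mm == tr$displacement_mm[1]
  list(observed = observed[first_d, ], reference = reference,
       displacements = displacements,
       report = accuracy_report(observed[first_d, ], reference, displacements))
}

.transient_kernel <- function(t_rel, amplitude, rise_ms, decay_ms) {
  # difference of exponentials normalized so the peak equals `amplitude`
  stopifnot(decay_ms > rise_ms)
  t_peak <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  peak <- exp(-t_peak / decay_ms) - exp(-t_peak / rise_ms)
  out <- ifelse(t_rel >= 0,
                (exp(-t_rel / decay_ms) - exp(-t_rel / rise_ms)) / peak, 0)
  amplitude * out
}

#' Generate a synthetic photometry trace
#'
#' Generative model for the delta-F/F chain:
#' `F_ex(t) = B(t) + F0(t) + sum of transient kernels + noise`, where
#' `B(t)` is the instrument (dark) background and `F0(t)` the bleaching
#' baseline, both single exponentials; the dark segment is `B(t) + noise`.
#' Transients are difference-of-exponential kernels normalized so each
#' peak equals its stated amplitude (chosen for an analytic peak value).
#' A reference channel without transients is generated alongside.
#'
#' @param baseline List `(A, tau_ms, C)` of the bleaching baseline `F0`.
#' @param transients `data.frame` with `t_ms`, `amplitude`, `rise_ms`,
#'   `decay_ms` (may have zero rows).
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param fs_hz Sampling rate (Hz), default 200.
#' @param duration_ms Recording duration (ms).
#' @param dark List `(A, tau_ms, C)` of the instrument background `B`.
#' @param dark_ms Dark-segment duration (ms), default 60 s.
#' @param seed RNG seed.
#' @return A [photometry_trace()]; attribute `"ground_truth"` carries the
#'   generative parameters and per-transient true peak delta-F/F
#'   (`amplitude / F0(t)` at the transient peak).
#' @export
synth_photometry <- function(baseline = list(A = 2, tau_ms = 300e3, C = 10),
                             transients = data.frame(),
                             noise_sd = 0.02, fs_hz = 200,
                             duration_ms = 120e3,
                             dark = list(A = 1, tau_ms = 200e3, C = 2),
                             dark_ms = 60e3, seed = 1) {
  stopifnot(noise_sd >= 0, duration_ms > 0)
  if (nrow(transients)) {
    stopifnot(all(c("t_ms", "amplitude", "rise_ms", "decay_ms") %in%
                  names(transients)),
              all(transients$amplitude >= 0))
  }
  set.seed(seed)
  dt <- 1000 / fs_hz
  t <- seq(0, duration_ms, by = dt)
  B <- dark$A * exp(-t / dark$tau_ms) + dark$C
  F0 <- baseline$A * exp(-t / baseline$tau_ms) + baseline$C
  sig <- F0
  true_peaks <- numeric(0)
  if (nrow(transients)) {
    for (k in seq_len(nrow(transients))) {
      tr <- transients[k, ]
      sig <- sig + .transient_kernel(t - tr$t_ms, tr$amplitude,
                                     tr$rise_ms, tr$decay_ms)
      t_peak <- tr$rise_ms * tr$decay_ms / (tr$decay_ms - tr$rise_ms) *
        log(tr$decay_ms / tr$rise_ms)
      F0_at <- baseline$A * exp(-(tr$t_ms + t_peak) / baseline$tau_ms) + baseline$C
      true_peaks <- c(true_peaks, tr$amplitude / F0_at)
    }
  }
  F_ex <- B + sig + stats::rnorm(length(t), 0, noise_sd)
  F_ref <- 0.8 * B + 0.5 * mean(F0) + stats::rnorm(length(t), 0, noise_sd)
  t_dark <- seq(0, dark_ms, by = dt)
  dark_df <- data.frame(
    t_ms = t_dark,
    F = dark$A * exp(-t_dark / dark$tau_ms) + dark$C +
      stats::rnorm(length(t_dark), 0, noise_sd))
  out <- photometry_trace(t, F_ex, F_ref, dark = dark_df, fs_hz = fs_hz)
  attr(out, "ground_truth") <- list(baseline = baseline, dark = dark,
                                    transients = transients,
                                    true_peak_dff = true_peaks)
  out
}
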