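# Shared fixtures: scripted tracks and independent rule-replaying oracles.

DT60 <- 1000 / 60

# Constant-speed slow dither inside the looming trigger zone, from t = 0.
# Radius 30 mm around the zone center keeps the agent well inside the
# Ø250 mm zone; angular step sets the speed (~36 mm/s at 0.02 rad/sample).
zone_dither_track <- function(duration_ms, layout = make_layout("looming"),
                              ang_step = 0.02) {
  n <- round(duration_ms / DT60)
  th <- (0:n) * ang_step
  ctr <- layout$arena_center
  position_track((0:n) * DT60, ctr[["x"]] + 30 * cos(th),
                 ctr[["y"]] + 30 * sin(th))
}

# Sit outside the zone until habituation ends, then cross the zone center
# in a straight line at constant speed v_mms.
zone_approach_track <- function(v_mms, layout = make_layout("looming"),
                                habituation_ms = 300e3) {
  ctr <- layout$arena_center
  start_x <- ctr[["x"]] - layout$regions$open_area$r + 30
  n_wait <- ceiling(habituation_ms / DT60)
  travel_mm <- 2 * layout$regions$open_area$r - 60
  n_move <- ceiling(travel_mm / (v_mms * DT60 / 1000))
  t <- (0:(n_wait + n_move)) * DT60
  x <- c(rep(start_x, n_wait + 1),
         start_x + (1:n_move) * v_mms * DT60 / 1000)
  position_track(t, x, rep(ctr[["y"]], length(t)))
}

# A track that dithers in the trigger zone, then (entry_at_ms) dashes into
# the refuge, optionally exits again (exit_at_ms) and re-enters
# (reentry_at_ms). Positions move instantaneously between stations; only
# refuge membership timing matters for the shock rules.
shock_scenario_track <- function(duration_ms, entry_at_ms = NA,
                                 exit_at_ms = NA, reentry_at_ms = NA,
                                 layout = make_layout("looming")) {
  n <- round(duration_ms / DT60)
  t <- (0:n) * DT60
  ctr <- layout$arena_center
  th <- (0:n) * 0.02
  x <- ctr[["x"]] + 30 * cos(th)
  y <- ctr[["y"]] + 30 * sin(th)
  inref <- rep(FALSE, n + 1)
  if (!is.na(entry_at_ms)) {
    inref[t >= entry_at_ms] <- TRUE
    if (!is.na(exit_at_ms)) {
      inref[t >= exit_at_ms] <- FALSE
      if (!is.na(reentry_at_ms)) inref[t >= reentry_at_ms] <- TRUE
    }
  }
  x[inref] <- 200; y[inref] <- ctr[["y"]]
  position_track(t, x, y)
}

# Independent sample-by-sample replay of the foot-shock episode rules for a
# single trigger: on at the trigger; off on refuge entry; on again on exit
# before trigger + rearm; unconditional off at trigger + max_on.
shock_oracle <- function(track, layout, trigger_ms, spec = shock_spec()) {
  v <- track[track$valid, , drop = FALSE]
  inside <- region_contains(layout$regions$refuge, v$x_mm, v$y_mm)
  t_stop <- trigger_ms + spec$max_on_ms
  ev_t <- trigger_ms; ev_k <- "shock_on"
  i0 <- which(v$t_ms >= trigger_ms)[1]
  on <- !(length(inside) && inside[i0])
  if (!on) { ev_t <- c(ev_t, trigger_ms); ev_k <- c(ev_k, "shock_off") }
  prev <- inside[i0]
  for (j in seq(i0, nrow(v))) {
    if (v$t_ms[j] >= t_stop) break
    if (on && inside[j] && !prev) {
      ev_t <- c(ev_t, v$t_ms[j]); ev_k <- c(ev_k, "shock_off"); on <- FALSE
    } else if (!on && !inside[j] && prev &&
               v$t_ms[j] < trigger_ms + spec$rearm_window_ms) {
      ev_t <- c(ev_t, v$t_ms[j]); ev_k <- c(ev_k, "shock_on"); on <- TRUE
    }
    prev <- inside[j]
  }
  if (on) { ev_t <- c(ev_t, t_stop); ev_k <- c(ev_k, "shock_off") }
  data.frame(t_ms = ev_t, kind = ev_k)
}

# Independent linear scan of the trigger gates (habituation, zone, speed,
# refractory, cap) used as the oracle against evaluate_triggers.
trigger_oracle <- function(track, layout, cfg) {
  v <- track[track$valid, , drop = FALSE]
  zone <- layout$regions[[cfg$zone]]
  raw <- c(NA, sqrt(diff(v$x_mm)^2 + diff(v$y_mm)^2) / diff(v$t_ms) * 1000)
  out <- numeric(0); last <- -Inf; cnt <- 0
  end_t <- if (is.finite(cfg$session_max_ms)) cfg$session_max_ms else Inf
  for (i in seq_len(nrow(v))) {
    t <- v$t_ms[i]
    if (t > end_t) break
    if (i < 2) next
    sm <- mean(raw[max(2, i - cfg$speed_window + 1):i])
    if (t >= cfg$habituation_ms &&
        region_contains(zone, v$x_mm[i], v$y_mm[i]) &&
        sm < cfg$speed_max_mms &&
        t - last >= cfg$refractory_ms && cnt < cfg$max_triggers) {
      cnt <- cnt + 1; last <- t; out <- c(out, t)
      if (cnt == 1 && !is.na(cfg$session_end_after_trigger_ms))
        end_t <- min(end_t, t + cfg$session_end_after_trigger_ms)
    }
  }
  out
}

# Random convex quad: unit square corners plus bounded jitter, rejection-
# sampled for convexity.
random_convex_quad <- function() {
  repeat {
    q <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)) +
      matrix(stats::runif(8, -0.25, 0.25), 4, 2)
    per <- q[c(1, 2, 4, 3), ]
    s <- vapply(1:4, function(k) {
      a <- per[k, ]; b <- per[k %% 4 + 1, ]; c0 <- per[(k + 1) %% 4 + 1, ]
      (b[1] - a[1]) * (c0[2] - a[2]) - (b[2] - a[2]) * (c0[1] - a[1])
    }, 0)
    if (all(s > 0.05) || all(s < -0.05)) return(q)
  }
}
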