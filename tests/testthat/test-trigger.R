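lay <- make_layout("looming")

test_that("the looming trigger gates on habituation, zone and speed", {
  # slow movement in the zone from t = 0: first trigger exactly at
  # habituation end, session_end 120 s later
  tr <- zone_dither_track(8 * 60e3)
  ev <- evaluate_triggers(tr, lay, trigger_config("looming"))
  trig <- ev[ev$kind == "trigger", ]
  expect_equal(nrow(trig), 1)
  expect_equal(trig$t_ms, 300e3, tolerance = 1e-9)
  expect_equal(ev$t_ms[ev$kind == "session_end"], 420e3, tolerance = 1e-9)

  # slow pass through the zone after habituation triggers; fast pass does not
  ev <- evaluate_triggers(zone_approach_track(100), lay, trigger_config("looming"))
  expect_equal(sum(ev$kind == "trigger"), 1)
  ev <- evaluate_triggers(zone_approach_track(200), lay, trigger_config("looming"))
  expect_equal(sum(ev$kind == "trigger"), 0)

  expect_error(evaluate_triggers(tr, lay, trigger_config("looming", zone = "nope")),
               "not found")
})

test_that("opto sessions respect the refractory interval and the 5-trigger cap", {
  tr <- zone_dither_track(40 * 60e3)
  ev <- evaluate_triggers(tr, lay, trigger_config("opto"))
  tt <- ev$t_ms[ev$kind == "trigger"]
  expect_equal(length(tt), 5)
  expect_true(all(diff(tt) >= 180e3 - 1e-6))
  expect_gte(min(tt), 300e3)
  # all five fall inside the 30-min active window after habituation
  expect_lte(max(tt), 300e3 + 1800e3)
})

test_that("trigger decisions match a rule-replaying oracle on adversarial tracks", {
  withr::local_seed(13)
  for (rep in 1:8) {
    # random dwell segments alternating between zone and periphery at
    # random speeds around the threshold
    n_seg <- 30
    segs <- data.frame(
      in_zone = stats::runif(n_seg) > 0.4,
      v = stats::runif(n_seg, 0, 300),
      dur = stats::runif(n_seg, 500, 8000))
    xs <- ys <- ts <- numeric(0)
    t <- 0; x <- 650; y <- 150
    for (k in seq_len(n_seg)) {
      tgt_y <- if (segs$in_zone[k]) 260 else 100  # 100 is outside the zone
      n <- max(2, round(segs$dur[k] / DT60))
      ang <- stats::runif(1, 0, 2 * pi)
      step <- segs$v[k] * DT60 / 1000
      for (j in 1:n) {
        x <- 650 + 0.9 * (x - 650 + cos(ang) * step) %% 60 - 30
        y <- tgt_y + (j %% 5) * step / 5
        ts <- c(ts, t); xs <- c(xs, x); ys <- c(ys, y)
        t <- t + DT60
      }
    }
    tr <- position_track(ts, xs, ys)
    cfg <- trigger_config("looming", habituation_ms = 10e3,
                          refractory_ms = 20e3, max_triggers = 4,
                          session_end_after_trigger_ms = NA,
                          session_max_ms = Inf)
    got <- evaluate_triggers(tr, lay, cfg)
    expect_equal(got$t_ms[got$kind == "trigger"], trigger_oracle(tr, lay, cfg))
    tt <- got$t_ms[got$kind == "trigger"]
    expect_true(all(tt >= cfg$habituation_ms))
    if (length(tt) > 1) expect_true(all(diff(tt) >= cfg$refractory_ms))
    expect_lte(length(tt), cfg$max_triggers)
  }
})

test_that("the looming timeline follows the 2-to-40 degree, 15-repeat schedule", {
  tl <- looming_timeline(looming_spec(), t0 = 0)
  expect_equal(tl$events$kind, c("stim_on", "stim_off"))
  expect_equal(tl$events$t_ms, c(0, 5670))  # 15*(300+50) + 14*30
  expect_equal(tl$theta_deg(150), 21)       # expansion midpoint
  expect_equal(tl$diameter_mm(0), 2 * 460 * tan(1 * pi / 180), tolerance = 1e-9)
  expect_equal(tl$theta_deg(310), 40)       # hold phase
  expect_true(is.na(tl$theta_deg(360)))     # gap phase

  # theta is continuous and non-decreasing within each expansion, and
  # d(t) = 2 h tan(theta/2) to 1e-9 relative
  t <- seq(0, 300, by = 0.5)
  th <- tl$theta_deg(t)
  expect_true(all(diff(th) >= 0))
  expect_equal(tl$diameter_mm(t), 2 * 460 * tan(th / 2 * pi / 180),
               tolerance = 1e-9)
  # offset timeline shifts rigidly
  tl2 <- looming_timeline(looming_spec(), t0 = 1000)
  expect_equal(tl2$events$t_ms, c(1000, 6670))
  expect_equal(tl2$theta_deg(1150), 21)
})

test_that("the foot-shock state machine follows the stop/re-arm/lockout rules", {
  spec <- shock_spec()
  trig <- event_log(400e3, "trigger", "")

  # entry at T+1200 ms, never exits: [on@T, off@T+1200]
  tr <- shock_scenario_track(500e3, entry_at_ms = 401200)
  ev <- shock_controller(tr, lay, trig, spec)
  sh <- ev[ev$kind %in% c("shock_on", "shock_off"), ]
  expect_equal(sh$kind, c("shock_on", "shock_off"))
  expect_equal(sh$t_ms, c(400e3, 401200), tolerance = DT60)

  # entry@T+2000, exit@T+4000, re-entry@T+4800: on/off/on/off
  tr <- shock_scenario_track(500e3, 402000, 404000, 404800)
  ev <- shock_controller(tr, lay, trig, spec)
  sh <- ev[ev$kind %in% c("shock_on", "shock_off"), ]
  expect_equal(sh$kind, c("shock_on", "shock_off", "shock_on", "shock_off"))
  expect_equal(sh$t_ms, c(400e3, 402000, 404000, 404800), tolerance = DT60)

  # never enters the refuge: unconditional stop 6 s after the trigger
  tr <- shock_scenario_track(500e3)
  ev <- shock_controller(tr, lay, trig, spec)
  sh <- ev[ev$kind %in% c("shock_on", "shock_off"), ]
  expect_equal(sh$t_ms, c(400e3, 406e3))

  # exit after the re-arm window: no second shock
  tr <- shock_scenario_track(500e3, 402000, 407000)
  ev <- shock_controller(tr, lay, trig, spec)
  expect_equal(sum(ev$kind == "shock_on"), 1)
})

test_that("shock episodes match the sample-replaying oracle on random scenarios", {
  withr::local_seed(29)
  spec <- shock_spec()
  for (rep in 1:20) {
    T0 <- 400e3
    entry <- if (stats::runif(1) < 0.8) T0 + stats::runif(1, 100, 8000) else NA
    ext <- if (!is.na(entry) && stats::runif(1) < 0.7)
      entry + stats::runif(1, 100, 6000) else NA
    re <- if (!is.na(ext) && stats::runif(1) < 0.7)
      ext + stats::runif(1, 100, 3000) else NA
    tr <- shock_scenario_track(430e3, entry, ext, re)
    got <- shock_controller(tr, lay, event_log(T0, "trigger", ""), spec)
    got <- got[got$kind %in% c("shock_on", "shock_off"), c("t_ms", "kind")]
    want <- shock_oracle(tr, lay, T0, spec)
    expect_equal(got$kind, want$kind)
    expect_equal(got$t_ms, want$t_ms)

    # shock is never on while the animal is inside the refuge
    v <- tr[tr$valid, ]
    inside <- region_contains(lay$regions$refuge, v$x_mm, v$y_mm)
    on_iv <- matrix(c(got$t_ms[got$kind == "shock_on"],
                      got$t_ms[got$kind == "shock_off"]), ncol = 2)
    for (r in seq_len(nrow(on_iv)))
      expect_false(any(inside[v$t_ms > on_iv[r, 1] & v$t_ms < on_iv[r, 2]]))
    # cumulative on-time per trigger never exceeds max_on
    expect_lte(sum(on_iv[, 2] - on_iv[, 1]), spec$max_on_ms)
  }
})

test_that("optogenetic trains pulse at 20 Hz for the whole epoch", {
  ev <- opto_train(opto_spec(), 0)
  pulses <- ev$t_ms[ev$kind == "pulse"]
  expect_equal(length(pulses), 50)
  expect_equal(pulses[1], 0)
  expect_equal(max(pulses), 2450)
  expect_equal(ev$t_ms[ev$kind == "stim_off"], 2500)
  expect_equal(unique(diff(pulses)), 50)

  ev <- opto_train(opto_spec(epoch_ms = 100), 0)
  expect_equal(sum(ev$kind == "pulse"), 2)

  expect_error(opto_spec(pulse_ms = 60), "overlap")
})

test_that("identical track and config give bit-identical event logs", {
  tr <- zone_dither_track(7 * 60e3)
  cfg <- trigger_config("looming")
  expect_identical(evaluate_triggers(tr, lay, cfg),
                   evaluate_triggers(tr, lay, cfg))
})
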