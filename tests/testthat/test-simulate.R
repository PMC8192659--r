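lay <- make_layout("looming")

test_that("exploration is reproducible, bounded, and degenerate without noise", {
  p <- mouse_sim_params()
  t1 <- explore_trajectory(p, lay, 60e3, seed = 4)
  t2 <- explore_trajectory(p, lay, 60e3, seed = 4)
  expect_identical(t1, t2)
  expect_false(identical(t1, explore_trajectory(p, lay, 60e3, seed = 5)))

  # positions never leave the open area (body-inset reflection)
  oa <- lay$regions$open_area
  d <- sqrt((t1$x_mm - oa$cx)^2 + (t1$y_mm - oa$cy)^2)
  expect_true(all(d <= oa$r + 1e-9))

  still <- explore_trajectory(mouse_sim_params(noise = 0), lay, 5e3, seed = 1)
  expect_equal(unique(still$x_mm), oa$cx)
  expect_equal(unique(still$y_mm), oa$cy)

  expect_error(explore_trajectory(p, lay, 10), "2 samples")
})

test_that("closed-loop flights reproduce commanded latency and straightness", {
  # fast reaction, straight dash: latency ~ distance / speed
  p <- mouse_sim_params(flight_speed_mms = 600, react_ms = 0, noise = 1)
  ses <- closed_loop_session(p, lay, trigger_config("looming"), seed = 11)
  expect_equal(nrow(ses$ground_truth), 1)
  trig <- ses$ground_truth
  ev <- event_log(trig$trigger_t_ms, "trigger", "")
  fs <- flight_summary(ses$track, ev, lay)
  d0 <- sqrt((trig$trigger_x - lay$refuge_entry[["x"]])^2 +
             (trig$trigger_y - lay$refuge_entry[["y"]])^2)
  expect_equal(fs$latency_ms, d0 / 600 * 1000, tolerance = 0.15)
  expect_equal(fs$distance_ratio, 1, tolerance = 0.05)
  expect_equal(fs$max_speed_mms, 600, tolerance = 0.05)
  # mean speed * latency ~ path length (discretization only)
  expect_equal(fs$mean_speed_mms * fs$latency_ms / 1000, fs$path_mm,
               tolerance = 0.02)
})

test_that("batch trigger evaluation reproduces the online closed-loop decisions", {
  for (seed in c(2, 8, 21)) {
    ses <- closed_loop_session(mouse_sim_params(), lay,
                               trigger_config("looming"), seed = seed)
    batch <- evaluate_triggers(ses$track, lay, trigger_config("looming"))
    expect_equal(batch$t_ms[batch$kind == "trigger"],
                 ses$ground_truth$trigger_t_ms)
  }
})

test_that("negative-control sessions never fire and occupancy spreads out", {
  ses <- closed_loop_session(mouse_sim_params(), lay, trigger_config("looming"),
                             duration_ms = 600e3, seed = 3,
                             triggers_active = FALSE)
  expect_equal(nrow(ses$ground_truth), 0)
  expect_equal(sum(ses$events$kind == "trigger"), 0)
  # the agent explores the whole open area rather than hugging one spot
  expect_gt(stats::sd(ses$track$x_mm), 40)
  expect_gt(stats::sd(ses$track$y_mm), 40)
})

test_that("session stimuli are scheduled at each trigger", {
  p <- mouse_sim_params()
  ses <- closed_loop_session(p, lay, trigger_config("looming"), looming_spec(),
                             seed = 7)
  t0 <- ses$ground_truth$trigger_t_ms[1]
  expect_equal(ses$events$t_ms[ses$events$kind == "stim_on"], t0)
  expect_equal(ses$events$t_ms[ses$events$kind == "stim_off"], t0 + 5670)
  # session ends 120 s after the trigger
  expect_equal(ses$events$t_ms[ses$events$kind == "session_end"], t0 + 120e3)
})

test_that("the cube protocol enumerates 400 displacement trials with truth", {
  g <- beam_grid()
  prot <- cube_protocol(g)
  expect_equal(nrow(prot$truth), 20 * 4 * 5)
  expect_equal(length(prot$snapshots), 400)
  expect_equal(sort(unique(prot$truth$displacement_mm)), c(1, 2, 5, 10))

  # zero displacement decodes to zero measured displacement
  prot0 <- cube_protocol(g, positions = cbind(450, 260), displacements_mm = 0,
                         repeats = 1)
  dec <- decode_cube_protocol(prot0)
  expect_equal(dec$displacements$measured_mm, 0)

  # cube pushed over the frame edge is rejected
  expect_error(cube_protocol(g, positions = cbind(895, 260)), "frame")
})

test_that("synthetic photometry is reproducible with analytic transient peaks", {
  trn <- data.frame(t_ms = 30e3, amplitude = 1, rise_ms = 50, decay_ms = 400)
  a <- synth_photometry(transients = trn, seed = 6, duration_ms = 60e3)
  b <- synth_photometry(transients = trn, seed = 6, duration_ms = 60e3)
  expect_identical(a$F_ex, b$F_ex)
  expect_identical(a$dark$F, b$dark$F)

  # noiseless, flat baseline: the raw signal peak equals the stated amplitude
  flat <- synth_photometry(baseline = list(A = 0, tau_ms = 1e9, C = 10),
                           dark = list(A = 0, tau_ms = 1e9, C = 0),
                           transients = trn, noise_sd = 0, duration_ms = 60e3)
  expect_equal(max(flat$F_ex) - 10, 1, tolerance = 1e-3)
  expect_error(synth_photometry(transients = transform(trn, amplitude = -1)),
               "amplitude")
})
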