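lay <- make_layout("looming")

test_that("instantaneous speed reproduces the 0.15 m/s threshold geometry", {
  # 2.5 mm per 16.667 ms sample is exactly 150 mm/s
  tr <- position_track((0:10) * 50 / 3, (0:10) * 2.5, rep(0, 11))
  sp <- instantaneous_speed(tr)
  expect_equal(sp$v_mms[-1], rep(150, 10))
  expect_equal(sp$a_mms2[-(1:2)], rep(0, 9))

  tr <- position_track((0:5) * 16.7, rep(3, 6), rep(4, 6))
  expect_equal(instantaneous_speed(tr)$v_mms[-1], rep(0, 5))

  expect_error(instantaneous_speed(position_track(0, 1, 1)),
               "insufficient data")
})

test_that("occupancy is the in-region share of total time", {
  z <- region_disk("z", 0, 0, 50)
  t <- (0:9) * 100
  tr <- position_track(t, c(rep(0, 5), rep(100, 5)), rep(0, 10))
  expect_equal(occupancy_fraction(tr, z), 5 / 9)  # 5 of 9 left-samples inside
  tr_in <- position_track(t, rep(0, 10), rep(0, 10))
  expect_equal(occupancy_fraction(tr_in, z), 1)
  tr_out <- position_track(t, rep(100, 10), rep(0, 10))
  expect_equal(occupancy_fraction(tr_out, z), 0)
  # invariant under time shift and 2x decimation
  tr2 <- position_track(t + 5000, tr$x_mm, tr$y_mm)
  expect_equal(occupancy_fraction(tr2, z), occupancy_fraction(tr, z))
})

test_that("flight summaries measure latency, hiding, ratio and speeds", {
  # two-leg right-angle path: 300 mm down then 400 mm left into the refuge
  ent <- lay$refuge_entry
  p0 <- c(ent[["x"]] + 400, ent[["y"]] + 300)
  leg1 <- cbind(p0[1], seq(p0[2], ent[["y"]], length.out = 31))
  leg2 <- cbind(seq(p0[1], ent[["x"]] - 1, length.out = 41), ent[["y"]])
  pts <- rbind(leg1, leg2[-1, ])
  tr <- position_track(seq_len(nrow(pts)) * 100 - 100, pts[, 1], pts[, 2])
  ev <- event_log(0, "trigger", "")
  fs <- flight_summary(tr, ev, lay)
  expect_equal(fs$distance_ratio, 700 / 500, tolerance = 0.01)
  expect_equal(fs$path_mm, 700, tolerance = 1)
  # mean speed * latency recovers the path length
  expect_equal(fs$mean_speed_mms * fs$latency_ms / 1000, fs$path_mm,
               tolerance = fs$path_mm * 0.02)

  # straight flight: ratio exactly 1
  pts <- cbind(seq(p0[1], ent[["x"]] - 1, length.out = 50), ent[["y"]])
  tr <- position_track(seq_len(50) * 100 - 100, pts[, 1], pts[, 2])
  fs <- flight_summary(tr, ev, lay)
  expect_equal(fs$distance_ratio, 1)

  # never entering the refuge is a valid outcome with NA latency
  tr <- position_track((0:10) * 100, 650 + (0:10), rep(260, 11))
  fs <- flight_summary(tr, ev, lay)
  expect_true(is.na(fs$latency_ms))
  expect_true(is.na(fs$distance_ratio))

  expect_error(flight_summary(tr, event_log(), lay), "exactly one trigger")
})

test_that("distance ratio is at least one on random escape paths", {
  withr::local_seed(17)
  ev <- event_log(0, "trigger", "")
  for (rep in 1:300) {
    n_mid <- sample(1:12, 1)
    start <- c(stats::runif(1, 420, 880), stats::runif(1, 30, 490))
    mids <- cbind(stats::runif(n_mid, 420, 880), stats::runif(n_mid, 30, 490))
    end <- c(stats::runif(1, 50, 390), stats::runif(1, 215, 305))  # in refuge
    pts <- rbind(start, mids, end)
    tr <- position_track(seq_len(nrow(pts)) * 50 - 50, pts[, 1], pts[, 2])
    fs <- flight_summary(tr, ev, lay)
    expect_gte(fs$distance_ratio, 1 - 1e-12)
  }
})

test_that("hiding time truncated at session end is flagged", {
  ent <- lay$refuge_entry
  x <- c(seq(ent[["x"]] + 200, ent[["x"]] - 50, length.out = 20), rep(200, 30))
  tr <- position_track(seq_len(50) * 100, x, rep(ent[["y"]], 50))
  fs <- flight_summary(tr, event_log(100, "trigger", ""), lay)
  expect_true(fs$hiding_truncated)
  expect_gt(fs$hiding_ms, 0)
})

test_that("event-aligned averages pool trials on a common grid", {
  t <- seq(0, 10e3, by = 10)
  s1 <- data.frame(t_ms = t, v = rep(100, length(t)))
  s2 <- data.frame(t_ms = t, v = rep(200, length(t)))
  ea <- event_aligned_average(list(s1, s2), onsets = 5000, window = c(1000, 2000))
  expect_true(all(ea$mean == 150))
  expect_true(all(ea$sem == 50))
  expect_equal(unique(ea$n), 2)

  # identical trials: dispersion zero
  ea <- event_aligned_average(s1, onsets = c(3000, 6000), window = c(500, 500))
  expect_true(all(ea$mean == 100))
  expect_true(all(ea$sd == 0))

  # onset too close to the start is dropped and reported
  ea <- event_aligned_average(s1, onsets = c(10, 5000), window = c(1000, 1000))
  expect_equal(ea$dropped, 1)
  expect_equal(unique(ea$n), 1)
  expect_error(event_aligned_average(s1, onsets = 10, window = c(1000, 1000)),
               "no usable trials")
})

test_that("session metrics tabulate every region and attach the flight", {
  ses <- closed_loop_session(mouse_sim_params(), lay, trigger_config("looming"),
                             seed = 5)
  tab <- session_metrics(ses$track, ses$events, lay)
  expect_setequal(tab$region, names(lay$regions))
  expect_true(all(tab$occupancy >= 0 & tab$occupancy <= 1))
  expect_s3_class(attr(tab, "flight"), "flight_summary")
})
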