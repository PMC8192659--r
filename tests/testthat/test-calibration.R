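test_that("inverse bilinear is exact on the identity quad and at corners", {
  q <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(inverse_bilinear(c(0.25, 0.5), q), c(0.25, 0.5))
  expect_equal(inverse_bilinear(c(0, 0), q), c(0, 0))
  expect_equal(inverse_bilinear(c(1, 0), q), c(1, 0))
  expect_equal(inverse_bilinear(c(0, 1), q), c(0, 1))
  expect_equal(inverse_bilinear(c(1, 1), q), c(1, 1))
  expect_error(inverse_bilinear(c(5, 5), q), "outside")
  expect_error(inverse_bilinear(c(0, 0), matrix(0, 4, 2)), "degenerate")
})

test_that("forward-then-inverse is the identity on random convex quads", {
  withr::local_seed(31)
  for (rep in 1:500) {
    q <- random_convex_quad()
    uv <- stats::runif(2)
    p <- forward_bilinear(uv, q)
    expect_equal(inverse_bilinear(p, q), uv, tolerance = 1e-9)
  }
})

test_that("grid mappings handle identity, translation and smooth distortion", {
  ref <- reference_lattice(6, 9, 40)

  m <- build_mapping(cal_grid(ref$x, ref$y, ref$x, ref$y))
  pts <- cbind(stats::runif(50, 1, 319), stats::runif(50, 1, 199))
  got <- m(pts[, 1], pts[, 2])
  expect_lt(max(abs(got - pts)), 1e-12)

  m <- build_mapping(cal_grid(ref$x, ref$y, ref$x + 13.5, ref$y - 7.25))
  got <- m(pts[, 1] + 13.5, pts[, 2] - 7.25)
  expect_equal(got, pts, tolerance = 1e-9, ignore_attr = TRUE)

  # barrel-like distortion on a 12 x 22 lattice (264 corners): corners are
  # interpolation nodes and map back exactly
  ref <- reference_lattice(12, 22, 40)
  cx <- mean(range(ref$x)); cy <- mean(range(ref$y))
  r2 <- ((ref$x - cx)^2 + (ref$y - cy)^2) / 1e6
  obs <- list(x = cx + (ref$x - cx) * (1 - 0.08 * r2),
              y = cy + (ref$y - cy) * (1 - 0.08 * r2))
  expect_equal(length(ref$x), 264)
  m <- build_mapping(cal_grid(ref$x, ref$y, obs$x, obs$y))
  idx <- cbind(sample(2:11, 20, TRUE), sample(2:21, 20, TRUE))
  for (k in 1:20) {
    i <- idx[k, 1]; j <- idx[k, 2]
    got <- m(obs$x[i, j], obs$y[i, j])
    expect_equal(as.numeric(got), c(ref$x[i, j], ref$y[i, j]),
                 tolerance = 1e-9)
  }
})

.cell <- function(g, i, j) {
  rbind(c(g$x[i, j], g$y[i, j]), c(g$x[i, j + 1], g$y[i, j + 1]),
        c(g$x[i + 1, j], g$y[i + 1, j]), c(g$x[i + 1, j + 1], g$y[i + 1, j + 1]))
}

test_that("mapping is continuous across shared cell edges", {
  withr::local_seed(41)
  ref <- reference_lattice(4, 4, 40)
  obs <- list(x = ref$x + matrix(stats::runif(16, -6, 6), 4, 4),
              y = ref$y + matrix(stats::runif(16, -6, 6), 4, 4))
  g <- cal_grid(ref$x, ref$y, obs$x, obs$y)
  m <- build_mapping(g)
  # points on the shared edge between cells (1,1) and (1,2)
  for (w in seq(0.05, 0.95, by = 0.1)) {
    p <- c((1 - w) * obs$x[1, 2] + w * obs$x[2, 2],
           (1 - w) * obs$y[1, 2] + w * obs$y[2, 2])
    left <- forward_bilinear(inverse_bilinear(p, .cell(obs, 1, 1)),
                             .cell(ref, 1, 1))
    right <- forward_bilinear(inverse_bilinear(p, .cell(obs, 1, 2)),
                              .cell(ref, 1, 2))
    expect_equal(left, right, tolerance = 1e-9)
  }
})

test_that("accuracy reports summarize per-position and per-displacement error", {
  refp <- data.frame(position = 1:3, x = c(0, 100, 200), y = c(0, 0, 0))
  obs <- data.frame(position = rep(1:3, each = 2), repeat_idx = rep(1:2, 3),
                    x = rep(c(0, 100, 200), each = 2),
                    y = rep(0, 6))
  rep0 <- accuracy_report(obs, refp)
  expect_true(all(rep0$positions$mean_mm == 0))

  # constant 1 mm offset: position error 1 everywhere, displacement error 0
  obs$x <- obs$x + 1
  disp <- data.frame(position = rep(1:3, 2), displacement_mm = rep(c(5, 10), each = 3),
                     repeat_idx = 1, measured_mm = rep(c(5, 10), each = 3))
  rep1 <- accuracy_report(obs, refp, disp)
  expect_true(all(rep1$positions$mean_mm == 1))
  expect_true(all(rep1$positions$sem_mm == 0))
  expect_true(all(rep1$displacements$mean_abs_error_mm == 0))

  expect_error(accuracy_report(transform(obs, position = position + 10), refp),
               "missing")
})

test_that("beam decode error stays flat while the camera error grows outward", {
  g <- beam_grid()
  prot <- cube_protocol(g)
  dec <- decode_cube_protocol(prot)
  expect_true(all(dec$report$positions$mean_mm <= 1 + 1e-9))
  expect_true(all(dec$report$displacements$max_abs_error_mm <= g$pitch_mm + 1e-9))

  # camera comparator: binned mean error increases with distance to center
  ctr <- c(g$width_mm / 2, g$height_mm / 2)
  pos <- prot$positions
  cam <- camera_decode(pos[, 1], pos[, 2], cam_center = ctr)
  err <- sqrt(rowSums((cam - pos)^2))
  dist <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
  bins <- cut(dist, breaks = 4)
  mean_err <- tapply(err, bins, mean)
  mean_err <- mean_err[!is.na(mean_err)]
  expect_true(all(diff(mean_err) > 0))
  # and the infrared decode error does not trend with distance
  ir_err <- dec$report$positions$mean_mm[order(as.numeric(dec$report$positions$position))]
  expect_lt(max(ir_err) - min(ir_err), g$pitch_mm / 2)
})
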