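#' Invert the bilinear map of a convex quadrilateral
#'
#' The bilinear map of a quad with corners `p00, p10, p01, p11` is
#' `P(u, v) = (1-u)(1-v) p00 + u (1-v) p10 + (1-u) v p01 + u v p11`.
#' Its inverse reduces to a quadratic in `v` (solved analytically), with
#' `u` recovered linearly. When two real roots exist, the root with both
#' coordinates in the unit square (within `1e-9` slack) wins, ties broken
#' toward the smaller `u` — fixed so results are deterministic.
#'
#' @param point Length-2 numeric `(x, y)` inside the quad.
#' @param quad 4 x 2 matrix of corners in row order `p00, p10, p01, p11`.
#' @return Length-2 numeric `(u, v)` in the unit square.
#' @examples
#' q <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' inverse_bilinear(c(0.25, 0.5), q)  # (0.25, 0.5)
#' @export
inverse_bilinear <- function(point, quad) {
  stopifnot(length(point) == 2, is.matrix(quad), all(dim(quad) == c(4, 2)))
  E <- quad[2, ] - quad[1, ]
  Fv <- quad[3, ] - quad[1, ]
  G <- quad[1, ] - quad[2, ] - quad[3, ] + quad[4, ]
  if (all(abs(E) < 1e-12) || all(abs(Fv) < 1e-12))
    stop("degenerate quad: coincident corners")
  H <- point - quad[1, ]
  cross <- function(p, q) p[1] * q[2] - p[2] * q[1]
  a <- cross(G, Fv)
  b <- cross(H, G) + cross(E, Fv)
  c0 <- cross(H, E)
  eps <- 1e-12 * max(1, sum(abs(quad)))
  vs <- if (abs(a) < eps) {
    if (abs(b) < eps) stop("degenerate quad: bilinear map is singular")
    -c0 / b
  } else {
    disc <- b * b - 4 * a * c0
    if (disc < 0) {
      if (disc > -1e-9 * max(b * b, 1)) disc <- 0
      else stop("point is outside the quad (no real inverse)")
    }
    sq <- sqrt(disc)
    c((-b + sq) / (2 * a), (-b - sq) / (2 * a))
  }
  u_of_v <- function(v) {
    dx <- E[1] + v * G[1]
    dy <- E[2] + v * G[2]
    if (abs(dx) >= abs(dy)) (H[1] - v * Fv[1]) / dx else (H[2] - v * Fv[2]) / dy
  }
  cand <- lapply(vs, function(v) c(u = u_of_v(v), v = v))
  slack <- 1e-9
  ok <- vapply(cand, function(uv)
    all(uv >= -slack & uv <= 1 + slack), TRUE)
  if (!any(ok)) stop("point maps outside the unit square (outside the quad)")
  cand <- cand[ok]
  uv <- cand[[which.min(vapply(cand, `[`, 0, 1))]]
  pmin(pmax(unname(uv), 0), 1)
}

#' Forward bilinear interpolation
#'
#' @param uv Length-2 `(u, v)` in the unit square.
#' @param quad 4 x 2 corner matrix, rows `p00, p10, p01, p11`.
#' @return Length-2 point.
#' @export
forward_bilinear <- function(uv, quad) {
  u <- uv[1]; v <- uv[2]
  as.numeric((1 - u) * (1 - v) * quad[1, ] + u * (1 - v) * quad[2, ] +
             (1 - u) * v * quad[3, ] + u * v * quad[4, ])
}

#' Calibration grid: congruent reference and observed corner lattices
#'
#' Wraps a checkerboard corner lattice (reference = true corner
#' coordinates, e.g. on a 40-mm pitch; observed = the same corners as
#' measured by the system under test). The corner count is layout-
#' dependent — a 12 x 22 lattice gives the 264 corners of a full-frame
#' 40-mm checkerboard — and any congruent lattice pair is accepted.
#'
#' @param ref_x,ref_y Matrices (rows = lattice rows) of reference corner
#'   coordinates (mm).
#' @param obs_x,obs_y Congruent matrices of observed coordinates.
#' @return An object of class `"cal_grid"`.
#' @export
cal_grid <- function(ref_x, ref_y, obs_x, obs_y) {
  dims <- dim(ref_x)
  if (!all(vapply(list(ref_y, obs_x, obs_y),
                  function(m) identical(dim(m), dims), TRUE)))
    stop("reference and observed lattices must be congruent in shape")
  if (any(dims < 2)) stop("lattice needs >= 2 corners per axis")
  structure(list(ref_x = ref_x, ref_y = ref_y, obs_x = obs_x, obs_y = obs_y,
                 nrow = dims[1], ncol = dims[2]),
            class = "cal_grid")
}

#' Build a regular reference lattice
#'
#' @param nrow,ncol Corner counts.
#' @param pitch_mm Checkerboard pitch (mm), default 40.
#' @param origin Lattice origin `(x, y)`.
#' @return List of matrices `x`, `y`.
#' @export
reference_lattice <- function(nrow, ncol, pitch_mm = 40, origin = c(0, 0)) {
  list(x = outer(rep(1, nrow), origin[1] + (seq_len(ncol) - 1) * pitch_mm),
       y = outer(origin[2] + (seq_len(nrow) - 1) * pitch_mm, rep(1, ncol)))
}

.cell_quad <- function(gx, gy, i, j) {
  rbind(c(gx[i, j],     gy[i, j]),
        c(gx[i, j + 1], gy[i, j + 1]),
        c(gx[i + 1, j], gy[i + 1, j]),
        c(gx[i + 1, j + 1], gy[i + 1, j + 1]))
}

.point_in_quad <- function(p, quad, tol = 1e-9) {
  # convex quad in perimeter order p00 p10 p11 p01
  per <- quad[c(1, 2, 4, 3), , drop = FALSE]
  s <- vapply(1:4, function(k) {
    a <- per[k, ]; b <- per[if (k == 4) 1 else k + 1, ]
    (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }, 0)
  scale <- max(abs(per)) + 1
  all(s >= -tol * scale) || all(s <= tol * scale)
}

#' Build an observed-to-reference coordinate mapping
#'
#' Piecewise inverse bilinear interpolation over the calibration grid: a
#' query point is located in its containing observed cell, inverted to
#' cell-local `(u, v)`, and forward-mapped into the corresponding
#' reference cell. The map is continuous across shared cell edges and
#' exact at every lattice corner.
#'
#' @param grid A [cal_grid()].
#' @return A function `f(x, y)` (vectorized) returning a 2-column matrix
#'   of reference coordinates; points outside the observed grid hull
#'   raise an out-of-grid error.
#' @export
build_mapping <- function(grid) {
  stopifnot(inherits(grid, "cal_grid"))
  force(grid)
  map_one <- function(x, y) {
    p <- c(x, y)
    for (i in seq_len(grid$nrow - 1)) for (j in seq_len(grid$ncol - 1)) {
      q_obs <- .cell_quad(grid$obs_x, grid$obs_y, i, j)
      if (.point_in_quad(p, q_obs)) {
        uv <- inverse_bilinear(p, q_obs)
        return(forward_bilinear(uv, .cell_quad(grid$ref_x, grid$ref_y, i, j)))
      }
    }
    stop("point (", x, ", ", y, ") is outside the calibration grid")
  }
  function(x, y) {
    out <- t(mapply(map_one, x, y))
    colnames(out) <- c("x", "y")
    out
  }
}

#' Accuracy and displacement-resolution report
#'
#' The accuracy protocol: an object is placed at a set of reference
#' positions, displaced by known amounts, and each manipulation is
#' repeated. The report gives, per position, the mean and SEM of the
#' Euclidean distance between measured and reference coordinates over
#' repeats, and per displacement magnitude the absolute error between the
#' measured and true displacement.
#'
#' @param observed `data.frame` with `position` (id), `repeat_idx`, `x`,
#'   `y` — measured base-position coordinates.
#' @param reference `data.frame` with `position`, `x`, `y` — true
#'   coordinates.
#' @param displacements Optional `data.frame` with `position`,
#'   `displacement_mm` (true magnitude), `repeat_idx`, `measured_mm`
#'   (measured magnitude).
#' @return A list of class `"accuracy_report"`: `positions`
#'   (`position`, `mean_mm`, `sem_mm`, `n`) and `displacements`
#'   (`displacement_mm`, `mean_abs_error_mm`, `max_abs_error_mm`, `n`).
#' @export
accuracy_report <- function(observed, reference, displacements = NULL) {
  stopifnot(all(c("position", "x", "y") %in% names(observed)),
            all(c("position", "x", "y") %in% names(reference)))
  ref_idx <- match(observed$position, reference$position)
  if (anyNA(ref_idx)) stop("observed position missing from the reference set")
  d <- sqrt((observed$x - reference$x[ref_idx])^2 +
            (observed$y - reference$y[ref_idx])^2)
  pos <- do.call(rbind, lapply(split(d, observed$position), function(v)
    data.frame(mean_mm = mean(v),
               sem_mm = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v))))
  pos <- cbind(position = rownames(pos), pos, row.names = NULL)
  disp <- NULL
  if (!is.null(displacements)) {
    stopifnot(all(c("displacement_mm", "measured_mm") %in% names(displacements)))
    err <- abs(displacements$measured_mm - displacements$displacement_mm)
    disp <- do.call(rbind, lapply(split(err, displacements$displacement_mm),
      function(v) data.frame(mean_abs_error_mm = mean(v),
                             max_abs_error_mm = max(v), n = length(v))))
    disp <- cbind(displacement_mm = as.numeric(rownames(disp)), disp,
                  row.names = NULL)
  }
  structure(list(positions = pos, displacements = disp),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\nPer-position error (mm):\n")
  print(x$positions)
  if (!is.null(x$displacements)) {
    cat("Per-displacement error (mm):\n")
    print(x$displacements)
  }
  invisible(x)
}

#' Pinhole-camera position estimate of a cube
#'
#' Synthetic comparator for the infrared decode: an overhead pinhole
#' camera at `cam_height_mm` above the floor projects the 8 corners of an
#' axis-aligned cube onto the floor plane, and the estimated position is
#' the center of the projected silhouette's bounding box. Because the
#' cube's top face projects outward from the optical axis, the estimate is
#' biased away from the camera center, and the bias grows with distance —
#' the visual-angle deviation a monocular camera cannot avoid, and the
#' qualitative contrast with the position-independent beam-grid decode.
#'
#' @param x,y Cube center coordinates (mm), vectorized.
#' @param cube_mm Cube edge length (mm), default 40.
#' @param cam_center Camera ground position `(x, y)`.
#' @param cam_height_mm Camera height above the floor (mm).
#' @return 2-column matrix of estimated positions.
#' @export
camera_decode <- function(x, y, cube_mm = 40, cam_center = c(450, 260),
                          cam_height_mm = 1500) {
  stopifnot(cam_height_mm > cube_mm)
  h <- cube_mm / 2
  one <- function(cx, cy) {
    est <- numeric(2)
    for (axis in 1:2) {
      c0 <- if (axis == 1) cx else cy
      cc <- cam_center[axis]
      lo <- hi <- numeric(0)
      for (z in c(0, cube_mm)) {
        s <- cam_height_mm / (cam_height_mm - z)   # projection onto floor plane
        lo <- c(lo, cc + (c0 - h - cc) * s)
        hi <- c(hi, cc + (c0 + h - cc) * s)
      }
      est[axis] <- (min(lo) + max(hi)) / 2
    }
    est
  }
  out <- t(mapply(one, x, y))
  colnames(out) <- c("x", "y")
  out
}
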