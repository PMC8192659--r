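#' Arena regions
#'
#' Regions are named planar sets used for occupancy, entry counting, and
#' trigger-zone tests. All membership tests are closed (boundaries count as
#' inside).
#'
#' @param name Region name.
#' @param x0,y0,x1,y1 Rectangle corners (mm), `x0 < x1`, `y0 < y1`.
#' @return An object of class `"ir_region"`.
#' @export
region_rect <- function(name, x0, y0, x1, y1) {
  if (!(x0 < x1 && y0 < y1)) stop("degenerate rectangle '", name, "'")
  structure(list(name = name, type = "rect",
                 x0 = x0, y0 = y0, x1 = x1, y1 = y1),
            class = "ir_region")
}

#' @rdname region_rect
#' @param cx,cy Disk center (mm).
#' @param r Disk radius (mm), positive.
#' @export
region_disk <- function(name, cx, cy, r) {
  if (!(r > 0)) stop("degenerate disk '", name, "': r must be positive")
  structure(list(name = name, type = "disk", cx = cx, cy = cy, r = r),
            class = "ir_region")
}

#' @rdname region_rect
#' @param xs,ys Polygon vertex coordinates (simple, non-self-intersecting).
#' @export
region_polygon <- function(name, xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3)
    stop("polygon '", name, "' needs >= 3 vertices")
  if (.polygon_self_intersects(xs, ys))
    stop("polygon '", name, "' is self-intersecting")
  structure(list(name = name, type = "polygon", xs = xs, ys = ys),
            class = "ir_region")
}

#' @export
print.ir_region <- function(x, ...) {
  desc <- switch(x$type,
    rect = sprintf("rect [%g,%g]x[%g,%g]", x$x0, x$x1, x$y0, x$y1),
    disk = sprintf("disk c=(%g,%g) r=%g", x$cx, x$cy, x$r),
    polygon = sprintf("polygon, %d vertices", length(x$xs)))
  cat(sprintf("<ir_region> %s: %s\n", x$name, desc))
  invisible(x)
}

.polygon_self_intersects <- function(xs, ys) {
  n <- length(xs)
  seg <- cbind(xs, ys, xs[c(2:n, 1)], ys[c(2:n, 1)])
  inter <- function(a, b) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) <= 1 || abs(i - j) == n - 1) next
    if (inter(seg[i, ], seg[j, ])) return(TRUE)
  }
  FALSE
}

#' Point-in-region test
#'
#' Vectorized over points; boundary points are inside (closed regions), with
#' a small tolerance for floating-point edge cases on polygon boundaries.
#'
#' @param region An `ir_region`.
#' @param x,y Point coordinates (mm), equal-length numeric vectors.
#' @return Logical vector.
#' @examples
#' z <- region_disk("zone", 0, 0, 125)
#' region_contains(z, c(125, 125.1), c(0, 0))  # TRUE FALSE
#' @export
region_contains <- function(region, x, y) {
  stopifnot(inherits(region, "ir_region"))
  switch(region$type,
    rect = x >= region$x0 & x <= region$x1 & y >= region$y0 & y <= region$y1,
    disk = (x - region$cx)^2 + (y - region$cy)^2 <= region$r^2,
    polygon = mapply(.point_in_polygon, x, y,
                     MoreArgs = list(xs = region$xs, ys = region$ys)))
}

.point_in_polygon <- function(px, py, xs, ys, tol = 1e-9) {
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    # boundary check: point on segment (i,j)
    dx <- xs[j] - xs[i]; dy <- ys[j] - ys[i]
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) ((px - xs[i]) * dx + (py - ys[i]) * dy) / len2 else 0
    t <- min(max(t, 0), 1)
    qx <- xs[i] + t * dx; qy <- ys[i] + t * dy
    if ((px - qx)^2 + (py - qy)^2 <= tol^2) return(TRUE)
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Paradigm presets. All dimensions in mm, from the apparatus descriptions:
# looming: circular open area diameter 500, trigger zone diameter 250
# concentric, refuge alley 400 x 100 attached; EPM: open/closed arms
# 235 x 50 around a 50 x 50 center; two-chamber: two 250 x 300 chambers,
# 100 x 100 food / no-food corner regions. Foot-shock and optogenetic
# paradigms reuse the looming geometry (only the floor/stimulus changes).
.LAYOUT_DEFAULTS <- list(
  looming = list(arena_d = 500, trigger_d = 250, refuge_l = 400, refuge_w = 100,
                 frame_w = 900, frame_h = 520),
  epm = list(arm_l = 235, arm_w = 50, center = 50, frame_w = 900, frame_h = 520),
  two_chamber = list(chamber_w = 250, chamber_h = 300, food_sz = 100,
                     frame_w = 900, frame_h = 520)
)

#' Build an arena layout preset
#'
#' Layouts carry the named regions each paradigm's analysis requires:
#' \describe{
#'   \item{looming / footshock / opto}{`open_area` (disk Ø500 mm),
#'     `trigger_zone` (concentric disk Ø250 mm), `refuge`
#'     (400 x 100 mm alley attached at the left of the open area). The
#'     foot-shock and optogenetic paradigms reuse the looming geometry.}
#'   \item{epm}{two open arms, two closed arms (235 x 50 mm each) and a
#'     50 x 50 mm `center`, arranged as a plus.}
#'   \item{two_chamber}{`left` and `right` chambers (250 x 300 mm each),
#'     `food_region` and `no_food_region` (100 x 100 mm corner squares).}
#' }
#' The layout records `refuge_entry`, the midpoint of the refuge doorway,
#' used as the flight target by the simulator and as the optional
#' distance-ratio denominator endpoint.
#'
#' @param paradigm One of `"looming"`, `"footshock"`, `"epm"`,
#'   `"two_chamber"`, `"opto"`.
#' @param overrides Named list of dimension overrides (see the preset fields
#'   in the source, e.g. `arena_d`, `trigger_d`, `refuge_l`, `refuge_w`,
#'   `arm_l`, `arm_w`, `chamber_w`, ...).
#' @return An object of class `"ir_layout"`: list with `name`, `regions`
#'   (named list of `ir_region`), `frame_w`, `frame_h`, and paradigm
#'   extras such as `refuge_entry`.
#' @examples
#' lay <- make_layout("looming")
#' lay$regions$trigger_zone$r  # 125
#' @export
make_layout <- function(paradigm, overrides = list()) {
  geom_key <- switch(paradigm,
    looming = , footshock = , opto = "looming",
    epm = "epm", two_chamber = "two_chamber",
    stop("unknown paradigm preset: '", paradigm, "'"))
  p <- utils::modifyList(.LAYOUT_DEFAULTS[[geom_key]], overrides)
  bad <- vapply(p, function(v) !is.numeric(v) || v <= 0, TRUE)
  if (any(bad)) stop("degenerate dimension override: ", names(p)[bad][1])

  if (geom_key == "looming") {
    r <- p$arena_d / 2
    cx <- p$refuge_l + r          # circle tangent to refuge doorway at x = refuge_l
    cy <- p$frame_h / 2
    if (p$trigger_d >= p$arena_d)
      stop("trigger zone must lie inside the open area")
    regions <- list(
      open_area = region_disk("open_area", cx, cy, r),
      trigger_zone = region_disk("trigger_zone", cx, cy, p$trigger_d / 2),
      refuge = region_rect("refuge", 0, cy - p$refuge_w / 2,
                           p$refuge_l, cy + p$refuge_w / 2))
    extras <- list(refuge_entry = c(x = p$refuge_l, y = cy),
                   arena_center = c(x = cx, y = cy))
  } else if (geom_key == "epm") {
    cx <- p$frame_w / 2; cy <- p$frame_h / 2; h <- p$center / 2
    if (p$arm_w > p$center)
      stop("arm width exceeds the central section")
    regions <- list(
      center = region_rect("center", cx - h, cy - h, cx + h, cy + h),
      open_arm_1 = region_rect("open_arm_1", cx - h - p$arm_l, cy - p$arm_w / 2,
                               cx - h, cy + p$arm_w / 2),
      open_arm_2 = region_rect("open_arm_2", cx + h, cy - p$arm_w / 2,
                               cx + h + p$arm_l, cy + p$arm_w / 2),
      closed_arm_1 = region_rect("closed_arm_1", cx - p$arm_w / 2, cy - h - p$arm_l,
                                 cx + p$arm_w / 2, cy - h),
      closed_arm_2 = region_rect("closed_arm_2", cx - p$arm_w / 2, cy + h,
                                 cx + p$arm_w / 2, cy + h + p$arm_l))
    extras <- list(arena_center = c(x = cx, y = cy))
  } else {
    w <- p$chamber_w; hgt <- p$chamber_h; f <- p$food_sz
    if (f > min(w, hgt)) stop("food region exceeds its chamber")
    regions <- list(
      left = region_rect("left", 0, 0, w, hgt),
      right = region_rect("right", w, 0, 2 * w, hgt),
      food_region = region_rect("food_region", 0, 0, f, f),
      no_food_region = region_rect("no_food_region", 2 * w - f, hgt - f, 2 * w, hgt))
    extras <- list(arena_center = c(x = w, y = hgt / 2))
  }
  structure(c(list(name = paradigm, regions = regions,
                   frame_w = p$frame_w, frame_h = p$frame_h), extras),
            class = "ir_layout")
}

#' @export
print.ir_layout <- function(x, ...) {
  cat(sprintf("<ir_layout> %s (frame %g x %g mm)\n", x$name, x$frame_w, x$frame_h))
  for (r in x$regions) print(r)
  invisible(x)
}

#' Detect region entries and exits along a track
#'
#' Scans valid samples in time order and emits a `region_entry` event at
#' each sample where the previous valid sample was outside and the current
#' one is inside, and symmetrically `region_exit`. A track that starts
#' inside the region counts an entry at its first valid sample, keeping
#' entry counts and occupancy bookkeeping consistent. Invalid samples are
#' skipped. An optional debounce (`min_dwell_ms`) suppresses visits and
#' excursions shorter than the given dwell; default 0 (off).
#'
#' @param track An [position_track()].
#' @param region An `ir_region`.
#' @param min_dwell_ms Minimum dwell (ms) for a crossing to register.
#' @return An [event_log()] of alternating `region_entry` / `region_exit`
#'   events with `region=<name>` payloads.
#' @export
region_crossings <- function(track, region, min_dwell_ms = 0) {
  stopifnot(inherits(track, "ir_track"), inherits(region, "ir_region"))
  v <- track[track$valid, , drop = FALSE]
  if (nrow(v) == 0) return(event_log())
  inside <- region_contains(region, v$x_mm, v$y_mm)
  if (min_dwell_ms > 0) inside <- .debounce(inside, v$t_ms, min_dwell_ms)
  # transitions, plus an initial entry when the track starts inside
  idx <- which(c(inside[1], diff(inside)) != 0)
  kinds <- ifelse(inside[idx], "region_entry", "region_exit")
  event_log(v$t_ms[idx], kinds,
            rep(payload(region = region$name), length(idx)))
}

.debounce <- function(inside, t_ms, min_dwell_ms) {
  # merge interior runs shorter than min_dwell into the preceding state
  repeat {
    r <- rle(inside)
    if (length(r$lengths) <= 2) return(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k_int <- seq_along(r$lengths)[-c(1, length(r$lengths))]
    dur <- t_ms[ends[k_int] + 1] - t_ms[starts[k_int]]
    short <- k_int[dur < min_dwell_ms]
    if (!length(short)) return(inside)
    k <- short[1]
    inside[starts[k]:ends[k]] <- r$values[k - 1]
  }
}
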