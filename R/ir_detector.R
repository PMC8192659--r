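#' Infrared beam grid
#'
#' The touch frame is modelled as two orthogonal banks of evenly spaced
#' beams. Beam `i` (0-based) on the x axis is the vertical line
#' `x = i * pitch_mm`; similarly on y. An occupant casts a shadow on every
#' beam line its footprint intersects, and its position is decoded as the
#' center of the enclosing rectangle of blocked beams.
#'
#' @param width_mm,height_mm Active area (mm). Default 900 x 520, a 42-inch
#'   16:9 frame.
#' @param pitch_mm Beam spacing (mm), identical on both axes. The decode
#'   quantization error is at most `pitch_mm / 2` per axis, so the default
#'   2 mm yields ~1 mm positional accuracy.
#' @param rate_hz Sampling rate (Hz), default 60.
#' @return An object of class `"beam_grid"` with beam counts `n_x`, `n_y`.
#' @export
beam_grid <- function(width_mm = 900, height_mm = 520, pitch_mm = 2,
                      rate_hz = 60) {
  stopifnot(pitch_mm > 0, rate_hz > 0, width_mm > 0, height_mm > 0)
  n_x <- floor(width_mm / pitch_mm) + 1L
  n_y <- floor(height_mm / pitch_mm) + 1L
  if (n_x < 2 || n_y < 2) stop("beam grid needs >= 2 beams per axis")
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 pitch_mm = pitch_mm, rate_hz = rate_hz,
                 n_x = as.integer(n_x), n_y = as.integer(n_y)),
            class = "beam_grid")
}

#' @export
print.beam_grid <- function(x, ...) {
  cat(sprintf("<beam_grid> %g x %g mm, pitch %g mm (%d x %d beams) @ %g Hz\n",
              x$width_mm, x$height_mm, x$pitch_mm, x$n_x, x$n_y, x$rate_hz))
  invisible(x)
}

#' Occupant footprints
#'
#' Convex 2-D cross-sections used to cast shadows on the beam grid: an
#' axis-aligned square (e.g. the 40-mm calibration cube) or a disk (a
#' mouse body approximation).
#'
#' @param x,y Footprint center (mm).
#' @param size_mm Square side length (mm).
#' @return An object of class `"ir_occupant"`.
#' @export
occupant_square <- function(x, y, size_mm = 40) {
  stopifnot(size_mm > 0)
  structure(list(shape = "square", x = x, y = y, size_mm = size_mm),
            class = "ir_occupant")
}

#' @rdname occupant_square
#' @param r_mm Disk radius (mm).
#' @export
occupant_disk <- function(x, y, r_mm = 20) {
  stopifnot(r_mm > 0)
  structure(list(shape = "disk", x = x, y = y, r_mm = r_mm),
            class = "ir_occupant")
}

.occupant_extent <- function(occ) {
  h <- if (occ$shape == "square") occ$size_mm / 2 else occ$r_mm
  list(x = c(occ$x - h, occ$x + h), y = c(occ$y - h, occ$y + h))
}

#' Simulate beam occlusion by an occupant
#'
#' A beam is blocked iff its line intersects the closed footprint. For both
#' supported convex footprints the blocked set on each axis is the set of
#' beam positions falling inside the footprint's interval on that axis.
#' A footprint entirely outside the active area yields an all-clear
#' snapshot (not an error).
#'
#' @param occupant An [occupant_square()] or [occupant_disk()].
#' @param grid A [beam_grid()].
#' @param t_ms Snapshot timestamp (ms).
#' @return An `"occlusion_snapshot"`: list with `t_ms`, logical `blocked_x`
#'   (length `n_x`), `blocked_y` (length `n_y`).
#' @examples
#' g <- beam_grid(pitch_mm = 2)
#' s <- occlude(occupant_square(100, 100, 40), g, 0)
#' sum(s$blocked_x)  # 21 beams: positions 80, 82, ..., 120
#' @export
occlude <- function(occupant, grid, t_ms = 0) {
  stopifnot(inherits(occupant, "ir_occupant"), inherits(grid, "beam_grid"))
  ext <- .occupant_extent(occupant)
  bx <- seq(0L, grid$n_x - 1L) * grid$pitch_mm
  by <- seq(0L, grid$n_y - 1L) * grid$pitch_mm
  structure(list(t_ms = t_ms,
                 blocked_x = bx >= ext$x[1] & bx <= ext$x[2],
                 blocked_y = by >= ext$y[1] & by <= ext$y[2]),
            class = "occlusion_snapshot")
}

#' Decode a position from an occlusion snapshot
#'
#' Implements the touch frame's position computation: the reported position
#' is the center of the smallest axis-aligned rectangle covering all
#' blocked beams. If either axis has no blocked beam the sample is invalid
#' (`valid = FALSE`), not an error. Disjoint blocked runs (which a single
#' animal does not produce) are covered by the overall enclosing rectangle.
#'
#' @param snapshot An occlusion snapshot.
#' @param grid The [beam_grid()] that produced it.
#' @return A one-row [position_track()].
#' @examples
#' g <- beam_grid(pitch_mm = 2)
#' decode_position(occlude(occupant_square(100, 100, 40), g), g)  # (100, 100)
#' @export
decode_position <- function(snapshot, grid) {
  stopifnot(inherits(snapshot, "occlusion_snapshot"), inherits(grid, "beam_grid"))
  if (length(snapshot$blocked_x) != grid$n_x ||
      length(snapshot$blocked_y) != grid$n_y)
    stop("snapshot beam counts do not match the grid")
  ix <- which(snapshot$blocked_x)
  iy <- which(snapshot$blocked_y)
  if (length(ix) && length(iy)) {
    x <- grid$pitch_mm * (min(ix) - 1 + max(ix) - 1) / 2
    y <- grid$pitch_mm * (min(iy) - 1 + max(iy) - 1) / 2
    position_track(snapshot$t_ms, x, y, TRUE)
  } else {
    position_track(snapshot$t_ms, NA_real_, NA_real_, FALSE)
  }
}

#' Decode a snapshot stream into a position track
#'
#' Batch form of the real-time decoding loop: one position record per
#' snapshot. Runs of invalid samples no longer than `max_gap_ms`,
#' bracketed by valid samples, are filled by linear interpolation and
#' flagged in the `interpolated` column; longer runs (and leading/trailing
#' runs) remain invalid.
#'
#' @param snapshots List of occlusion snapshots, time-ordered.
#' @param grid A [beam_grid()].
#' @param max_gap_ms Longest dropout to bridge (ms), default 500.
#' @return An [position_track()] with an extra logical `interpolated`
#'   column.
#' @export
stream_decode <- function(snapshots, grid, max_gap_ms = 500) {
  if (!length(snapshots))
    return(position_track(numeric(0), numeric(0), numeric(0), logical(0)))
  t <- vapply(snapshots, `[[`, 0, "t_ms")
  if (any(diff(t) <= 0)) stop("snapshots must be strictly time-ordered")
  rows <- lapply(snapshots, decode_position, grid = grid)
  tr <- do.call(rbind, lapply(rows, as.data.frame))
  interp <- rep(FALSE, nrow(tr))
  r <- rle(tr$valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in seq_along(r$lengths)) {
    if (r$values[k] || k == 1 || k == length(r$lengths)) next
    gap <- tr$t_ms[ends[k] + 1] - tr$t_ms[starts[k] - 1]
    if (gap > max_gap_ms) next
    i0 <- starts[k] - 1; i1 <- ends[k] + 1
    w <- (tr$t_ms[starts[k]:ends[k]] - tr$t_ms[i0]) / (tr$t_ms[i1] - tr$t_ms[i0])
    tr$x_mm[starts[k]:ends[k]] <- tr$x_mm[i0] + w * (tr$x_mm[i1] - tr$x_mm[i0])
    tr$y_mm[starts[k]:ends[k]] <- tr$y_mm[i0] + w * (tr$y_mm[i1] - tr$y_mm[i0])
    tr$valid[starts[k]:ends[k]] <- TRUE
    interp[starts[k]:ends[k]] <- TRUE
  }
  out <- position_track(tr$t_ms, tr$x_mm, tr$y_mm, tr$valid)
  out$interpolated <- interp
  out
}

#' Serialize occlusion snapshots to CSV
#'
#' Fixture format: one row per snapshot, `t_ms,<hex mask x>,<hex mask y>`,
#' each mask a big-endian hex string of the blocked-beam bit vector (bit 0 =
#' beam 0).
#'
#' @param snapshots List of occlusion snapshots.
#' @param path File path.
#' @param grid A [beam_grid()] (for validation on read).
#' @return `write_occlusion_csv` returns `path` invisibly;
#'   `read_occlusion_csv` returns a list of snapshots.
#' @export
write_occlusion_csv <- function(snapshots, path) {
  lines <- c("t_ms,mask_x,mask_y",
             vapply(snapshots, function(s)
               paste(.num_str(s$t_ms), .mask_to_hex(s$blocked_x),
                     .mask_to_hex(s$blocked_y), sep = ","), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_occlusion_csv
#' @export
read_occlusion_csv <- function(path, grid) {
  lines <- readLines(path)
  if (!length(lines) || trimws(lines[1]) != "t_ms,mask_x,mask_y")
    stop("unexpected occlusion-csv header in ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  lapply(body, function(ln) {
    f <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(f) != 3) stop("malformed occlusion row: ", ln)
    structure(list(t_ms = as.numeric(f[1]),
                   blocked_x = .hex_to_mask(f[2], grid$n_x),
                   blocked_y = .hex_to_mask(f[3], grid$n_y)),
              class = "occlusion_snapshot")
  })
}

.mask_to_hex <- function(bits) {
  n <- ceiling(length(bits) / 4) * 4
  bits <- c(bits, rep(FALSE, n - length(bits)))
  nib <- vapply(seq_len(n / 4), function(k) {
    b <- bits[(4 * k - 3):(4 * k)]
    sum(b * c(1L, 2L, 4L, 8L))
  }, 0)
  paste(format.hexmode(rev(nib)), collapse = "")
}

.hex_to_mask <- function(hex, n_beams) {
  nib <- rev(strtoi(strsplit(hex, "")[[1]], 16L))
  bits <- unlist(lapply(nib, function(v) bitwAnd(v, c(1L, 2L, 4L, 8L)) > 0))
  if (length(bits) < n_beams) bits <- c(bits, rep(FALSE, n_beams - length(bits)))
  bits[seq_len(n_beams)]
}
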