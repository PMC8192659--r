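#' Assemble a session configuration
#'
#' A session configuration bundles everything a simulated or analyzed
#' session needs: the arena layout preset (with dimension overrides), the
#' detector beam grid, the trigger rules, the stimulus specification, and
#' the RNG seed. Closed-loop paradigms (`looming`, `footshock`, `opto`)
#' get their protocol-default trigger config and stimulus spec; open-loop
#' paradigms (`epm`, `two_chamber`) have neither.
#'
#' @param paradigm Paradigm preset name.
#' @param arena Named list of layout dimension overrides.
#' @param detector Named list of [beam_grid()] overrides.
#' @param trigger Named list of [trigger_config()] overrides.
#' @param stimulus Named list of stimulus-spec overrides.
#' @param seed Integer RNG seed.
#' @return An object of class `"session_config"` with elements `paradigm`,
#'   `layout`, `grid`, `trigger`, `stimulus`, `seed`, and the raw override
#'   lists (for exact round-tripping).
#' @export
session_config <- function(paradigm, arena = list(), detector = list(),
                           trigger = list(), stimulus = list(), seed = 1) {
  closed_loop <- paradigm %in% c("looming", "footshock", "opto")
  layout <- make_layout(paradigm, arena)
  grid <- do.call(beam_grid, detector)
  trig <- NULL; stim <- NULL
  if (closed_loop) {
    trig <- do.call(trigger_config, c(list(paradigm = paradigm), trigger))
    if (is.null(layout$regions[[trig$zone]]))
      stop("trigger zone '", trig$zone, "' is not a region of the ",
           paradigm, " layout")
    stim <- switch(paradigm,
                   looming = do.call(looming_spec, stimulus),
                   footshock = do.call(shock_spec, stimulus),
                   opto = do.call(opto_spec, stimulus))
  } else if (length(trigger) || length(stimulus)) {
    stop("paradigm '", paradigm, "' is open-loop: no trigger/stimulus fields")
  }
  structure(list(paradigm = paradigm, layout = layout, grid = grid,
                 trigger = trig, stimulus = stim, seed = as.integer(seed),
                 overrides = list(arena = arena, detector = detector,
                                  trigger = trigger, stimulus = stimulus)),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> %s (seed %d)\n", x$paradigm, x$seed))
  print(x$grid)
  if (!is.null(x$trigger)) print(x$trigger)
  invisible(x)
}

.DUR_FIELDS <- c("habituation", "refractory", "session_end_after_trigger",
                 "session_max")

.normalize_trigger_overrides <- function(tr) {
  # accept both <field>_s and <field>_ms duration keys; store ms internally
  out <- list()
  for (key in names(tr)) {
    val <- tr[[key]]
    if (grepl("_s$", key) && sub("_s$", "", key) %in% .DUR_FIELDS) {
      if (is.numeric(val) && val < 0) stop("negative duration: ", key)
      out[[paste0(sub("_s$", "", key), "_ms")]] <- val * 1000
    } else {
      if (grepl("_ms$", key) && sub("_ms$", "", key) %in% .DUR_FIELDS &&
          is.numeric(val) && val < 0)
        stop("negative duration: ", key)
      out[[key]] <- val
    }
  }
  out
}

#' Load a session configuration from a YAML file
#'
#' The config file is human-editable YAML with one nesting level per
#' subsystem (`arena`, `detector`, `trigger`, `stimulus`) plus top-level
#' `paradigm` and `seed`. All omitted fields default to the paradigm
#' preset (for `looming`: trigger zone Ø250 mm, speed < 150 mm/s,
#' habituation 300 s, session end 120 s after the trigger). Trigger
#' durations may be given as `habituation_s` (seconds) or
#' `habituation_ms`, likewise for `refractory`, `session_end_after_trigger`
#' and `session_max`; a duration of 0 disables the gate. Top-level
#' duration keys are accepted as shorthand for the `trigger` block.
#'
#' @param path Path to the YAML file.
#' @return A [session_config()].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("paradigm: looming", f)
#' load_session_config(f)$trigger$speed_max_mms  # 150
#' @export
load_session_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$paradigm)) stop("config is missing 'paradigm'")
  known <- c("looming", "footshock", "opto", "epm", "two_chamber")
  if (!raw$paradigm %in% known)
    stop("unknown paradigm preset: '", raw$paradigm, "'")
  tr <- if (is.null(raw$trigger)) list() else raw$trigger
  # top-level duration shorthand
  for (key in names(raw)) {
    base <- sub("_(s|ms)$", "", key)
    if (base %in% .DUR_FIELDS) tr[[key]] <- raw[[key]]
  }
  tr <- .normalize_trigger_overrides(tr)
  session_config(paradigm = raw$paradigm,
                 arena = if (is.null(raw$arena)) list() else raw$arena,
                 detector = if (is.null(raw$detector)) list() else raw$detector,
                 trigger = tr,
                 stimulus = if (is.null(raw$stimulus)) list() else raw$stimulus,
                 seed = if (is.null(raw$seed)) 1L else raw$seed)
}

#' Write a session configuration to a YAML file
#'
#' Dumps a fully-specified configuration (every default resolved), so that
#' loading the dump reproduces the configuration exactly (defaulting is
#' idempotent).
#'
#' @param cfg A [session_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "session_config"))
  out <- list(paradigm = cfg$paradigm, seed = cfg$seed,
              arena = cfg$overrides$arena,
              detector = cfg$grid[c("width_mm", "height_mm", "pitch_mm", "rate_hz")])
  if (!is.null(cfg$trigger)) {
    tc <- unclass(cfg$trigger)
    tc$paradigm <- NULL
    tc <- tc[!vapply(tc, function(v) is.na(v) || is.infinite(v), TRUE)]
    out$trigger <- tc
    out$stimulus <- unclass(cfg$stimulus)
  }
  out <- Filter(function(v) !is.null(v) && (!is.list(v) || length(v)), out)
  yaml::write_yaml(out, path)
  invisible(path)
}
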