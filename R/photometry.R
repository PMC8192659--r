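#' Two-channel fiber-photometry trace
#'
#' Holds the 470-nm excitation channel (`F_ex`), the 410-nm reference
#' channel (`F_ref`), and the dark-background segment recorded with the
#' fiber tip in a dark box before the session (at least 60 s at the same
#' rate). The reference channel is ingested, filtered and exported but does
#' not enter the delta-F/F computation.
#'
#' @param t_ms Sample times (ms), strictly increasing.
#' @param F_ex,F_ref Fluorescence (arbitrary units); `F_ref` may be `NULL`.
#' @param dark A `data.frame` with `t_ms`, `F` — the dark segment.
#' @param fs_hz Sampling rate (Hz), default 200.
#' @return An object of class `"photometry_trace"`.
#' @export
photometry_trace <- function(t_ms, F_ex, F_ref = NULL, dark, fs_hz = 200) {
  stopifnot(fs_hz > 0, length(t_ms) == length(F_ex))
  if (any(diff(t_ms) <= 0)) stop("t_ms must be strictly increasing")
  if (!all(is.finite(F_ex))) stop("F_ex must be finite")
  if (!is.null(F_ref) && length(F_ref) != length(F_ex))
    stop("F_ref length mismatch")
  if (missing(dark) || is.null(dark)) {
    dark <- NULL
  } else {
    stopifnot(is.data.frame(dark), all(c("t_ms", "F") %in% names(dark)))
    if (diff(range(dark$t_ms)) < 60e3)
      stop("dark segment must span at least 60 s")
  }
  structure(list(t_ms = as.numeric(t_ms), F_ex = as.numeric(F_ex),
                 F_ref = if (is.null(F_ref)) NULL else as.numeric(F_ref),
                 dark = dark, fs_hz = fs_hz),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> %d samples @ %g Hz (%.1f s), dark %s\n",
              length(x$t_ms), x$fs_hz, diff(range(x$t_ms)) / 1000,
              if (is.null(x$dark)) "absent"
              else sprintf("%.1f s", diff(range(x$dark$t_ms)) / 1000)))
  invisible(x)
}

#' Zero-phase low-pass filter
#'
#' Second-order Butterworth applied forward and backward
#' (zero phase, unit DC gain). Used before exponential baseline fitting;
#' the delta-F/F itself is computed from the unfiltered signal.
#'
#' @param x Numeric series.
#' @param fs_hz Sampling rate (Hz).
#' @param cutoff_hz Cutoff frequency; must be below the Nyquist rate.
#' @return Filtered series, same length.
#' @export
lowpass <- function(x, fs_hz, cutoff_hz) {
  if (!(cutoff_hz > 0 && cutoff_hz < fs_hz / 2))
    stop("cutoff must lie in (0, fs/2)")
  bf <- signal::butter(2, cutoff_hz / (fs_hz / 2), type = "low")
  n <- length(x)
  # odd-reflection padding suppresses the filter's edge transients
  L <- min(n - 1, max(12, 9 * ceiling(fs_hz / cutoff_hz)))
  xp <- c(2 * x[1] - x[(L + 1):2], x, 2 * x[n] - x[(n - 1):(n - L)])
  y <- signal::filtfilt(bf, xp)
  as.numeric(y[(L + 1):(L + n)])
}

#' Fit a single exponential decay
#'
#' Least-squares fit of `f(t) = A * exp(-t / tau) + C` by
#' Levenberg-Marquardt. Initialization: `C` at the 5th percentile of the
#' series, `A` as the first sample minus `C`, `tau` as a third of the
#' segment duration; `tau` is bounded positive. These starts are fixed so
#' fits are reproducible.
#'
#' @param t_ms Sample times (ms).
#' @param y Series values (non-constant, >= 100 samples).
#' @return An object of class `"exp_fit"`: list with `A`, `tau_ms`, `C`,
#'   `rss`, and the `nls` fit object.
#' @examples
#' t <- seq(0, 60e3, by = 5)
#' f <- fit_exp_decay(t, 5 * exp(-t / 30e3) + 1)
#' c(f$A, f$tau_ms, f$C)  # 5, 30000, 1
#' @export
fit_exp_decay <- function(t_ms, y) {
  stopifnot(length(t_ms) == length(y))
  if (length(y) < 100) stop("exponential fit needs >= 100 samples")
  if (stats::sd(y) == 0)
    stop("series is constant: amplitude A is unidentifiable")
  C0 <- as.numeric(stats::quantile(y, 0.05))
  A0 <- y[1] - C0
  if (A0 == 0) A0 <- stats::sd(y)
  tau0 <- diff(range(t_ms)) / 3
  resid_fn <- function(p) y - (p[1] * exp(-t_ms / p[2]) + p[3])
  fit <- minpack.lm::nls.lm(par = c(A = A0, tau = tau0, C = C0),
                            fn = resid_fn,
                            lower = c(-Inf, 1e-6, -Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!fit$info %in% 1:4 || any(!is.finite(fit$par)))
    stop("exponential fit did not converge (start A=", signif(A0, 4),
         ", tau=", signif(tau0, 4), ", C=", signif(C0, 4), "; rss trail ",
         paste(signif(utils::tail(fit$rsstrace, 3), 4), collapse = " -> "),
         "): ", fit$message)
  p <- fit$par
  structure(list(A = unname(p["A"]), tau_ms = unname(p["tau"]),
                 C = unname(p["C"]), rss = fit$deviance, info = fit$info),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> A = %.6g, tau = %.6g ms, C = %.6g (rss %.4g)\n",
              x$A, x$tau_ms, x$C, x$rss))
  invisible(x)
}

#' @export
predict.exp_fit <- function(object, t_ms, ...) {
  object$A * exp(-t_ms / object$tau_ms) + object$C
}

#' Compute delta-F/F from a photometry trace
#'
#' The full processing chain:
#' \enumerate{
#'   \item low-pass filter the dark segment and fit a single exponential
#'     decay; extrapolate it over the recording as the instrument
#'     background `B(t)`;
#'   \item calcium fluorescence `F_ca(t) = F_ex(t) - B(t)`;
#'   \item low-pass filter `F_ca` and fit a second exponential decay — the
#'     bleaching baseline `F0(t)`;
#'   \item `dff(t) = (F_ca(t) - F0(t)) / F0(t)`.
#' }
#' Filtering is used only for the two baseline fits; the output delta-F/F
#' is computed from the unsmoothed `F_ca`.
#'
#' @param trace A [photometry_trace()] with a dark segment.
#' @param cutoff_hz Low-pass cutoff (Hz) for baseline estimation,
#'   default 2.
#' @return A `data.frame` of class `"dff_trace"` with `t_ms`, `dff`;
#'   attributes `dark_fit` and `baseline_fit` carry the two `exp_fit`s.
#' @export
compute_dff <- function(trace, cutoff_hz = 2) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (is.null(trace$dark))
    stop("dark segment missing: cannot estimate instrument background")
  dark_fit <- fit_exp_decay(trace$dark$t_ms,
                            lowpass(trace$dark$F, trace$fs_hz, cutoff_hz))
  B <- predict(dark_fit, trace$t_ms)
  F_ca <- trace$F_ex - B
  base_fit <- fit_exp_decay(trace$t_ms, lowpass(F_ca, trace$fs_hz, cutoff_hz))
  F0 <- predict(base_fit, trace$t_ms)
  if (any(F0 <= 0))
    stop("bleaching baseline F0 is non-positive at t_ms = ",
         trace$t_ms[which(F0 <= 0)[1]])
  out <- data.frame(t_ms = trace$t_ms, dff = (F_ca - F0) / F0)
  attr(out, "dark_fit") <- dark_fit
  attr(out, "baseline_fit") <- base_fit
  class(out) <- c("dff_trace", "data.frame")
  out
}

#' Event-aligned delta-F/F
#'
#' Aligns a delta-F/F trace to stimulus onsets: trial x time matrix plus
#' pointwise mean and dispersion, via [event_aligned_average()].
#'
#' @param dff A `dff_trace` (or any `data.frame` with `t_ms` and a value
#'   column).
#' @param onsets Event times (ms).
#' @param window `c(pre_ms, post_ms)`.
#' @return As [event_aligned_average()].
#' @export
event_aligned_dff <- function(dff, onsets, window) {
  event_aligned_average(as.data.frame(dff)[, c("t_ms", "dff")], onsets, window)
}

#' Read / write photometry CSV
#'
#' Trace files are CSV with header `t_ms,F_ex,F_ref`; the dark segment is
#' a separate CSV with header `t_ms,F`.
#'
#' @param path Trace file path.
#' @param dark_path Dark-segment file path.
#' @param fs_hz Sampling rate (Hz).
#' @return A [photometry_trace()].
#' @export
read_photometry_csv <- function(path, dark_path, fs_hz = 200) {
  tr <- utils::read.csv(path)
  stopifnot(all(c("t_ms", "F_ex") %in% names(tr)))
  dk <- utils::read.csv(dark_path)
  stopifnot(all(c("t_ms", "F") %in% names(dk)))
  photometry_trace(tr$t_ms, tr$F_ex,
                   if ("F_ref" %in% names(tr)) tr$F_ref else NULL,
                   dark = dk, fs_hz = fs_hz)
}

#' @rdname read_photometry_csv
#' @param trace A [photometry_trace()].
#' @export
write_photometry_csv <- function(trace, path, dark_path) {
  df <- data.frame(t_ms = trace$t_ms, F_ex = trace$F_ex)
  if (!is.null(trace$F_ref)) df$F_ref <- trace$F_ref
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(trace$dark[, c("t_ms", "F")], dark_path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
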