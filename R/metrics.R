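#' Phase-diagram metrics of a free-running trace
#'
#' Classifies a free-oscillator time trace into sustained, damped or
#' overdamped regimes over a fixed analysis horizon, using the metrics of
#' the free-oscillator phase diagram:
#' \itemize{
#'   \item `A_inf`: the normalized equilibrium amplitude — half the
#'     peak-to-trough span of the final full oscillation, normalized by the
#'     global maximum of the trace.
#'   \item `gamma`: the mean damping ratio of successive maxima,
#'     `mean(y_i / y_{i+1})`; ~1 for sustained, > 1 for damped oscillations.
#'     Computed only when at least two maxima are detected.
#'   \item `tau_eq`: the exponential equilibration time constant, fitted as
#'     `x(t) = x_inf + (x_0 - x_inf) * exp(-t / tau_eq)` when fewer than two
#'     maxima exist (strongly damped / overdamped traces).
#' }
#' The regime is `"sustained"` if `gamma <= 1 + tol` with at least two
#' maxima, `"damped"` if `gamma > 1 + tol`, and `"overdamped"` otherwise.
#' A flat trace is overdamped with `tau_eq = NA`.
#'
#' @param trace a `time_trace` or bare numeric signal.
#' @param channel channel name for a `time_trace`; default `"rep_a"`.
#' @param dt_h sampling interval (h) for a bare signal.
#' @param horizon_h analysis horizon (h); samples beyond it are dropped.
#'   Default 48.
#' @param exclude_initial_h initial window (h) excluded from the maxima used
#'   for `gamma` and `A_inf`; default 12. Traces start from an empty reactor,
#'   and the approach to the limit cycle would otherwise bias the damping
#'   ratio of genuinely sustained oscillations above 1. The `tau_eq` fit
#'   always uses the full horizon (the transient is what it measures).
#' @param tol tolerance on `gamma` separating sustained from damped;
#'   default 0.05.
#' @param prominence_frac peak prominence threshold as a fraction of the
#'   dynamic range (default 0.02), suppressing noise-born maxima.
#' @return An object of class `phase_metrics`: list with `A_inf`, `gamma`,
#'   `tau_eq_h`, `regime`, `n_maxima`.
#' @export
phase_metrics <- function(trace, channel = "rep_a", dt_h = NULL,
                          horizon_h = 48, exclude_initial_h = 12, tol = 0.05,
                          prominence_frac = 0.02) {
  sig <- resolve_signal(trace, channel, dt_h)
  t_h <- (seq_along(sig$x) - 1) * sig$dt_h
  keep <- t_h <= horizon_h
  x <- sig$x[keep]; t_h <- t_h[keep]

  out <- list(A_inf = NA_real_, gamma = NA_real_, tau_eq_h = NA_real_,
              regime = "overdamped", n_maxima = 0L)
  class(out) <- "phase_metrics"

  if (length(x) < 4 || diff(range(x)) == 0) return(out)  # flat trace

  imax <- find_local_maxima(x, prominence_frac)
  imin <- find_local_minima(x, prominence_frac)
  imax <- imax[t_h[imax] >= exclude_initial_h]
  imin <- imin[t_h[imin] >= exclude_initial_h]
  out$n_maxima <- length(imax)

  if (length(imax) >= 2) {
    y <- x[imax]
    out$gamma <- mean(y[-length(y)] / y[-1])
    # final full oscillation: last maximum and the trough preceding it
    troughs <- imin[imin > imax[length(imax) - 1] & imin < imax[length(imax)]]
    trough <- if (length(troughs)) min(x[troughs]) else min(x[imax[length(imax) - 1]:imax[length(imax)]])
    out$A_inf <- (x[imax[length(imax)]] - trough) / 2 / max(x)
    out$regime <- if (out$gamma <= 1 + tol) "sustained" else "damped"
    return(out)
  }

  # fewer than two maxima: exponential equilibration
  fit <- fit_least_squares(
    function(p) x - (p[["x_inf"]] + (p[["x0"]] - p[["x_inf"]]) * exp(-t_h / p[["tau"]])),
    start = c(x_inf = x[length(x)], x0 = x[1], tau = max(t_h) / 3),
    lower = c(x_inf = -Inf, x0 = -Inf, tau = 1e-6),
    upper = c(x_inf = Inf, x0 = Inf, tau = Inf),
    maxiter = 200)
  if (fit$converged) out$tau_eq_h <- fit$par[["tau"]]
  out$regime <- "overdamped"
  out
}

#' @export
print.phase_metrics <- function(x, ...) {
  cat(sprintf("Phase metrics: regime = %s (%d maxima)\n", x$regime, x$n_maxima))
  if (!is.na(x$gamma)) cat(sprintf("  gamma = %.3f, A_inf = %.3f\n", x$gamma, x$A_inf))
  if (!is.na(x$tau_eq_h)) cat(sprintf("  tau_eq = %.3g h\n", x$tau_eq_h))
  invisible(x)
}

#' Maximum return map
#'
#' Pairs each oscillation maximum with its successor, `(y_i, y_{i+1})`. An
#' exact m-cycle occupies exactly m distinct points of the map; chaotic
#' trajectories scatter.
#'
#' @param maxima numeric vector of maximum heights (>= 2 values), in order.
#' @return A data.frame with columns `y_i`, `y_next`.
#' @export
#' @examples
#' return_map(c(3, 7, 3, 7, 3))  # a 2-cycle: two distinct points
return_map <- function(maxima) {
  maxima <- as.numeric(maxima)
  if (length(maxima) < 2) stop("return_map: need at least 2 maxima", call. = FALSE)
  data.frame(y_i = maxima[-length(maxima)], y_next = maxima[-1])
}

#' Instantaneous refresh ratio from a reference-dye trace
#'
#' Estimates the realized per-cycle refresh ratio as `R_t = 1 - I_{t+1} /
#' I_t` from consecutive samples of a decaying reference-dye signal,
#' evaluated only where the predecessor intensity exceeds
#' `frac_threshold * max(I)` (low-intensity pairs are too noisy). Pairs that
#' span a feed spike make the signal rise and give `R_t <= 0`; they are
#' reported but flagged and excluded from summaries, as are values outside
#' the plausible band (-0.5, 1).
#'
#' @param ref_trace a single-channel `time_trace` (channel `"ref"` by
#'   default) or bare numeric intensity vector.
#' @param channel channel name for a `time_trace`.
#' @param dt_h sampling interval (h) for a bare vector.
#' @param frac_threshold mask threshold as a fraction of the maximum
#'   intensity; default 0.3.
#' @return An object of class `refresh_series`: data.frame with `cycle`,
#'   `time_h`, `R_t`, `mask` (predecessor above threshold) and `flagged`
#'   (spike-spanning or implausible). Empty (zero masked rows) if no point
#'   passes the mask.
#' @seealso [mean_refresh()] for windowed summaries.
#' @export
instantaneous_refresh <- function(ref_trace, channel = "ref", dt_h = NULL,
                                  frac_threshold = 0.3) {
  sig <- resolve_signal(ref_trace, channel, dt_h)
  x <- sig$x
  if (length(x) < 2) stop("instantaneous_refresh: need at least 2 samples", call. = FALSE)
  # background-subtracted noisy recordings can dip below zero; such samples
  # never pass the intensity mask, so they are tolerated rather than rejected
  n <- length(x) - 1L
  R_t <- 1 - x[-1] / x[-(n + 1L)]
  mask <- x[-(n + 1L)] > frac_threshold * max(x)
  flagged <- R_t < 0 | R_t >= 1 | !is.finite(R_t)
  out <- data.frame(cycle = seq_len(n) - 1L,
                    time_h = (seq_len(n) - 1L) * sig$dt_h,
                    R_t = R_t, mask = mask, flagged = flagged)
  class(out) <- c("refresh_series", "data.frame")
  out
}

#' Windowed mean of an instantaneous refresh-ratio series
#'
#' Mean of the masked, unflagged `R_t` values with `from_h <= time_h <
#' to_h`; the default window is the first 24 h, the customary baseline
#' against which late-run fatigue is quantified.
#'
#' @param rs a `refresh_series` from [instantaneous_refresh()].
#' @param from_h,to_h window bounds in hours.
#' @return The mean refresh ratio (NA if no usable points).
#' @export
mean_refresh <- function(rs, from_h = 0, to_h = 24) {
  stopifnot(inherits(rs, "refresh_series"))
  use <- rs$mask & !rs$flagged & rs$time_h >= from_h & rs$time_h < to_h
  if (!any(use)) return(NA_real_)
  mean(rs$R_t[use])
}

#' Calibration block for intensity normalization
#'
#' Holds the calibration and one-point reference intensities used to convert
#' background-subtracted fluorescence to concentration:
#' `c = (I - B)/(I0 - B0) * (I0_ref - B0_ref)/(I_ref - B_ref) * 1 uM`.
#' `I0`/`B0` come from the reactor's refresh-ratio calibration and
#' `I_ref`/`B_ref`, `I0_ref`/`B0_ref` from one-point reference measurements
#' of a known 1 uM standard.
#'
#' @param I0,B0 calibration sample and background intensities (a.u.).
#' @param I_ref,B_ref reference-standard intensities in the measurement
#'   context (a.u.).
#' @param I0_ref,B0_ref reference-standard intensities in the calibration
#'   context (a.u.).
#' @param B default background of the measured samples (a.u.).
#' @return An object of class `intensity_calibration`.
#' @export
intensity_calibration <- function(I0 = 1200, B0 = 200, I_ref = 900,
                                  B_ref = 100, I0_ref = 1100, B0_ref = 300,
                                  B = 100) {
  if ((I0 - B0) == 0 || (I_ref - B_ref) == 0) {
    stop("intensity_calibration: zero denominator after background subtraction",
         call. = FALSE)
  }
  cal <- list(I0 = I0, B0 = B0, I_ref = I_ref, B_ref = B_ref,
              I0_ref = I0_ref, B0_ref = B0_ref, B = B)
  class(cal) <- "intensity_calibration"
  cal
}

#' Convert measured intensity to concentration
#'
#' Applies the calibrated normalization
#' `c = (I - B)/(I0 - B0) * (I0_ref - B0_ref)/(I_ref - B_ref) * 1 uM`,
#' which is linear in the background-subtracted intensity and makes
#' concentrations comparable across experiments.
#'
#' @param I measured intensity (a.u.), vectorized.
#' @param cal an [intensity_calibration()].
#' @param B background of the measurement; defaults to `cal$B`.
#' @return Concentration in uM.
#' @seealso [concentration_to_intensity()] for the exact inverse.
#' @export
normalize_intensity <- function(I, cal = intensity_calibration(), B = cal$B) {
  stopifnot(inherits(cal, "intensity_calibration"))
  (I - B) / (cal$I0 - cal$B0) * (cal$I0_ref - cal$B0_ref) / (cal$I_ref - cal$B_ref)
}

#' @rdname normalize_intensity
#' @param c_uM concentration in uM.
#' @export
concentration_to_intensity <- function(c_uM, cal = intensity_calibration(),
                                       B = cal$B) {
  stopifnot(inherits(cal, "intensity_calibration"))
  B + c_uM * (cal$I0 - cal$B0) * (cal$I_ref - cal$B_ref) / (cal$I0_ref - cal$B0_ref)
}
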