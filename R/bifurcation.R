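#' Equilibrated cycle maxima of a forced trace, with degenerate-gap filling
#'
#' Detects the oscillation maxima of a per-cycle-sampled channel after
#' discarding the equilibration transient, and fills "degenerate" maxima:
#' when a forced orbit's secondary peak flattens into a shoulder it leaves no
#' local maximum in the sampled trace, yet still counts one forcing period
#' towards the rotation number. Wherever two consecutive detected maxima are
#' spaced by more than `gap_cycles` dilution cycles, additional maxima are
#' inserted at (approximately) the forcing cadence `spacing_cycles` within
#' the gap. Their heights are read from the trace at the inserted positions
#' (`height_source = "trace"`, the default, which preserves the distinct
#' height of the hidden shoulder), or linearly interpolated between the
#' flanking maxima (`height_source = "linear"`).
#'
#' @param trace a `time_trace` from [run_reactor()] (one sample per cycle).
#' @param channel channel to analyse; default `"h"` (endogenous repressor).
#' @param equilibration_cycles samples dropped from the start; default 500.
#' @param gap_cycles gap width (in cycles) above which degenerate maxima are
#'   interpolated; default 20.
#' @param spacing_cycles forcing cadence in cycles used for insertion;
#'   defaults to the protocol's `k` (or 16 if the trace has no protocol).
#' @param height_source `"trace"` or `"linear"` (see above).
#' @param prominence_frac peak prominence filter (fraction of dynamic
#'   range); default 0 (noiseless simulated traces).
#' @param min_spacing_cycles maxima closer than this many cycles are merged
#'   (the higher one kept); defaults to half the forcing cadence, since a
#'   forced orbit produces at most one maximum per input period. Noise on
#'   measured traces otherwise splits flat peaks in two.
#' @return A data.frame with columns `cycle` (position, in post-equilibration
#'   cycle units), `height`, `interpolated` (logical). The number of
#'   interpolated rows is available as `sum(...$interpolated)`.
#'   If no maxima exist after equilibration (monotone relaxation to a fixed
#'   point) an error of class `cfclock_fixed_point_error` is raised.
#' @export
detect_cycle_maxima <- function(trace, channel = "h",
                                equilibration_cycles = 500,
                                gap_cycles = 20, spacing_cycles = NULL,
                                height_source = c("trace", "linear"),
                                prominence_frac = 0,
                                min_spacing_cycles = NULL) {
  height_source <- match.arg(height_source)
  x <- if (is.data.frame(trace)) trace[[channel]] else as.numeric(trace)
  if (is.null(x)) stop("detect_cycle_maxima: no channel '", channel, "'", call. = FALSE)
  if (length(x) <= equilibration_cycles) {
    stop("detect_cycle_maxima: trace shorter than the equilibration window",
         call. = FALSE)
  }
  if (is.null(spacing_cycles)) {
    proto <- attr(trace, "protocol")
    spacing_cycles <- if (!is.null(proto)) proto$k else 16L
  }
  if (is.null(min_spacing_cycles)) min_spacing_cycles <- spacing_cycles / 2
  x <- x[-seq_len(equilibration_cycles)]
  pk <- find_local_maxima(x, prominence_frac)
  while (length(pk) > 1 && any(diff(pk) < min_spacing_cycles)) {
    j <- which(diff(pk) < min_spacing_cycles)[1]
    drop <- if (x[pk[j]] >= x[pk[j + 1]]) j + 1L else j
    pk <- pk[-drop]
  }
  if (!length(pk)) {
    stop(structure(class = c("cfclock_fixed_point_error", "error", "condition"),
                   list(message = "no maxima after equilibration: fixed-point regime",
                        call = NULL)))
  }
  pos <- integer(0); height <- numeric(0); interp <- logical(0)
  for (j in seq_along(pk)) {
    if (j > 1) {
      gap <- pk[j] - pk[j - 1]
      if (gap > gap_cycles) {
        n_ins <- round(gap / spacing_cycles) - 1L
        if (n_ins > 0) {
          at <- round(seq(pk[j - 1], pk[j], length.out = n_ins + 2L))[2:(n_ins + 1L)]
          hts <- if (height_source == "trace") {
            x[at]
          } else {
            x[pk[j - 1]] + (at - pk[j - 1]) / gap * (x[pk[j]] - x[pk[j - 1]])
          }
          pos <- c(pos, at); height <- c(height, hts)
          interp <- c(interp, rep(TRUE, n_ins))
        }
      }
    }
    pos <- c(pos, pk[j]); height <- c(height, x[pk[j]])
    interp <- c(interp, FALSE)
  }
  data.frame(cycle = pos, height = height, interpolated = interp)
}

#' Rotation number of a forced trajectory
#'
#' Classifies the periodicity of a sequence of oscillation maxima: the
#' rotation number `m` is the number of forcing periods the orbit needs to
#' return to its starting point. Heights are normalized by their maximum;
#' for each shift `k` the closure defect `DM(k)` aggregates the absolute
#' differences between the sequence and itself shifted by `k` entries, and
#' `m` is the smallest `k` with `DM(k) < threshold` (taking the smallest
#' passing `k` prevents multiples of the true period from being reported).
#' If no `k <= max_m` closes the orbit, the trajectory is classified
#' chaotic.
#'
#' The default aggregation is the maximum absolute pairwise difference —
#' the strictest closure test, appropriate for noiseless simulated maxima.
#' For maxima extracted from noisy recordings use `aggregate = "mean"`: the
#' maximum of n independent noise draws grows with n, so the max-norm
#' defect of a genuinely periodic but noisy sequence eventually exceeds any
#' fixed threshold, whereas the mean defect concentrates near the per-pair
#' noise level.
#'
#' @param maxima maximum heights in temporal order, typically
#'   `detect_cycle_maxima(...)$height`.
#' @param threshold closure threshold on the normalized heights;
#'   default 0.1.
#' @param max_m largest shift tested; default 32 (trajectories with
#'   `m > 32` are called chaotic).
#' @param aggregate `"max"` (default) or `"mean"` aggregation of the
#'   pairwise closure defects.
#' @return An object of class `rotation_result`: list with `m` (positive
#'   integer, or `NA` when chaotic), `chaotic` (logical), `delta_M` (the
#'   closure defects for `k = 1..max_m`), `threshold`, `n_maxima`.
#' @export
#' @examples
#' rotation_number(rep(c(1, 0.4), 40))$m   # 2-cycle
rotation_number <- function(maxima, threshold = 0.1, max_m = 32,
                            aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "max") max else mean
  h <- as.numeric(maxima)
  if (length(h) <= max_m) {
    stop("rotation_number: need more than max_m maxima (got ", length(h), ")",
         call. = FALSE)
  }
  hn <- h / max(h)
  dM <- vapply(seq_len(max_m), function(k) {
    agg_fun(abs(hn[seq_len(length(hn) - k)] - hn[seq_len(length(hn) - k) + k]))
  }, numeric(1))
  passing <- which(dM < threshold)
  if (!length(passing) && length(h) < 2 * max_m) {
    warning("rotation_number: chaotic call from fewer than 2*max_m maxima; ",
            "extend the simulation to confirm")
  }
  out <- list(
    m = if (length(passing)) as.integer(passing[1]) else NA_integer_,
    chaotic = !length(passing),
    delta_M = dM, threshold = threshold, n_maxima = length(h)
  )
  class(out) <- "rotation_result"
  out
}

#' @export
print.rotation_result <- function(x, ...) {
  if (x$chaotic) {
    cat(sprintf("Rotation number: no closure for k <= %d (chaotic), from %d maxima\n",
                length(x$delta_M), x$n_maxima))
  } else {
    cat(sprintf("Rotation number m = %d (DM = %.3g < %.2g), from %d maxima\n",
                x$m, x$delta_M[x$m], x$threshold, x$n_maxima))
  }
  invisible(x)
}

#' Simulate one forced operating point and classify it
#'
#' Runs the forced reactor at a given bifurcation parameter, extracts the
#' equilibrated endogenous-repressor maxima (with degenerate-gap filling)
#' and computes the rotation number.
#'
#' @param params an [oscillator_params] (see [preset_forced_oscillator()]).
#' @param lambda bifurcation parameter; the refresh ratio is derived via
#'   [lambda_to_refresh()] at the protocol's `k`.
#' @param analysis_cycles cycles retained for classification after the
#'   `equilibration_cycles` transient; default 576 (36 forcing periods, so a
#'   degenerate 2-cycle still leaves more than `max_m` maxima after gap
#'   filling).
#' @param equilibration_cycles discarded transient; default 500.
#' @param A_in,k,t_int forcing protocol (defaults 50 nM every 16th cycle of
#'   15 min, i.e. a 4 h zeitgeber).
#' @param channel channel whose maxima are classified; default `"h"`.
#' @param threshold,max_m,aggregate rotation-number settings, see
#'   [rotation_number()].
#' @param prominence_frac peak prominence filter forwarded to
#'   [detect_cycle_maxima()]; raise it (e.g. 0.02) for noisy channels.
#' @param ... further arguments passed to [run_reactor()].
#' @return A list with `lambda`, `trace`, `maxima` (data.frame), and
#'   `rotation` (a `rotation_result`).
#' @export
classify_forced_point <- function(params, lambda, analysis_cycles = 576,
                                  equilibration_cycles = 500, A_in = 50,
                                  k = 16, t_int = 15, channel = "h",
                                  threshold = 0.1, max_m = 32,
                                  aggregate = "max", prominence_frac = 0,
                                  ...) {
  proto <- forced_protocol(lambda,
                           n_cycles = equilibration_cycles + analysis_cycles,
                           A_in = A_in, k = k, t_int = t_int)
  trace <- run_reactor(params, proto, ...)
  maxima <- detect_cycle_maxima(trace, channel = channel,
                                equilibration_cycles = equilibration_cycles,
                                spacing_cycles = k,
                                prominence_frac = prominence_frac)
  rot <- rotation_number(maxima$height, threshold = threshold, max_m = max_m,
                         aggregate = aggregate)
  list(lambda = lambda, trace = trace, maxima = maxima, rotation = rot)
}

#' One-dimensional bifurcation scan over the forcing ratio
#'
#' For each requested bifurcation parameter the refresh ratio is set via the
#' inverse of the `lambda(R)` relation at fixed forcing cadence, the forced
#' reactor is simulated, and the equilibrated maxima heights of the
#' activator and endogenous repressor channels are recorded. Plotting the
#' heights against `lambda` exposes the period-doubling/halving structure
#' (single branch for entrained 1-cycles, 2 then 4 branches through the
#' doubling cascade, back to a single branch at high `lambda`).
#'
#' @inheritParams classify_forced_point
#' @param lambda_grid bifurcation parameters to scan (typically within
#'   (0, 2]).
#' @param channels channels whose maxima are recorded; default
#'   `c("a", "h")` (activator and endogenous repressor).
#' @return An object of class `bifurcation_scan`: a long data.frame with
#'   columns `lambda`, `channel`, `height`, `interpolated`, plus attributes
#'   `failed` (lambdas whose simulation or classification failed) and
#'   `settings`.
#' @export
bifurcation_1d <- function(params, lambda_grid, analysis_cycles = 512,
                           equilibration_cycles = 500, A_in = 50, k = 16,
                           t_int = 15, channels = c("a", "h"), ...) {
  stopifnot(inherits(params, "oscillator_params"))
  rows <- list(); failed <- numeric(0)
  for (lam in lambda_grid) {
    res <- tryCatch({
      proto <- forced_protocol(lam,
                               n_cycles = equilibration_cycles + analysis_cycles,
                               A_in = A_in, k = k, t_int = t_int)
      trace <- run_reactor(params, proto, ...)
      do.call(rbind, lapply(channels, function(ch) {
        mx <- detect_cycle_maxima(trace, channel = ch,
                                  equilibration_cycles = equilibration_cycles,
                                  spacing_cycles = k)
        data.frame(lambda = lam, channel = ch, height = mx$height,
                   interpolated = mx$interpolated)
      }))
    }, error = function(e) e)
    if (inherits(res, "error")) failed <- c(failed, lam) else rows[[length(rows) + 1]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lambda = numeric(0), channel = character(0),
               height = numeric(0), interpolated = logical(0))
  attr(out, "failed") <- failed
  attr(out, "settings") <- list(A_in = A_in, k = k, t_int = t_int,
                                equilibration_cycles = equilibration_cycles,
                                analysis_cycles = analysis_cycles)
  class(out) <- c("bifurcation_scan", "data.frame")
  out
}

#' Two-dimensional bifurcation scan over Hill coefficient and forcing ratio
#'
#' Computes the rotation number on a grid of (Hill coefficient `n`,
#' bifurcation parameter `lambda`), using the uniform-parameter constructor
#' for `n`. Increasing nonlinearity widens the bands of higher-order cycles
#' and eventually chaos; chaotic cells (no closure for `k <= max_m`) are
#' flagged distinctly.
#'
#' @inheritParams classify_forced_point
#' @param n_grid Hill coefficients to scan.
#' @param lambda_grid bifurcation parameters to scan.
#' @return An object of class `bifurcation_scan`: data.frame with columns
#'   `n`, `lambda`, `m` (NA for chaotic or failed cells), `chaotic`,
#'   `failed`.
#' @export
bifurcation_2d <- function(params, n_grid, lambda_grid,
                           analysis_cycles = 1088, equilibration_cycles = 500,
                           A_in = 50, k = 16, t_int = 15, channel = "h",
                           threshold = 0.1, max_m = 32, ...) {
  stopifnot(inherits(params, "oscillator_params"))
  grid <- expand.grid(n = n_grid, lambda = lambda_grid)
  grid$m <- NA_integer_; grid$chaotic <- FALSE; grid$failed <- FALSE
  for (i in seq_len(nrow(grid))) {
    p_i <- params
    p_i$n_a <- grid$n[i]; p_i$n_h <- grid$n[i]
    res <- tryCatch(
      classify_forced_point(p_i, grid$lambda[i],
                            analysis_cycles = analysis_cycles,
                            equilibration_cycles = equilibration_cycles,
                            A_in = A_in, k = k, t_int = t_int,
                            channel = channel, threshold = threshold,
                            max_m = max_m, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      grid$failed[i] <- TRUE
    } else {
      grid$m[i] <- res$rotation$m
      grid$chaotic[i] <- res$rotation$chaotic
    }
  }
  attr(grid, "settings") <- list(A_in = A_in, k = k, t_int = t_int,
                                 threshold = threshold, max_m = max_m)
  class(grid) <- c("bifurcation_scan", "data.frame")
  grid
}

#' Period sensitivity to individual model parameters
#'
#' Measures how the free-running period responds to a relative change
#' (default +30%) of each model parameter in turn, all others held at
#' baseline. Every variant is re-simulated in the semi-continuous reactor
#' and its period re-estimated from the ACF. Perturbing the dilution rate is
#' realized through the refresh ratio (`R' = 1 - exp(-delta' * t_int)`), the
#' control actually available on the reactor.
#'
#' @param params baseline [oscillator_params].
#' @param protocol a free-running [reactor_protocol] (no input); its length
#'   should cover several periods.
#' @param rel_change relative perturbation; default 0.3.
#' @param direction `"increase"` (default) or `"decrease"`.
#' @param channel channel used for period estimation; default `"rep_a"`.
#' @param ... passed to [run_reactor()].
#' @return A data.frame of class `sensitivity_result` with one row per
#'   parameter: `parameter`, `T_baseline_h`, `T_perturbed_h`, `delta_T_h`,
#'   `rel_delta_T`. A perturbed system without a detectable period yields
#'   NA in the perturbed columns.
#' @export
sensitivity_analysis <- function(params, protocol, rel_change = 0.3,
                                 direction = c("increase", "decrease"),
                                 channel = "rep_a", ...) {
  stopifnot(inherits(params, "oscillator_params"),
            inherits(protocol, "reactor_protocol"))
  direction <- match.arg(direction)
  fac <- if (direction == "increase") 1 + rel_change else 1 - rel_change
  base_est <- acf_period(run_reactor(params, protocol, ...), channel = channel)
  if (!base_est$ok) {
    stop("sensitivity_analysis: baseline simulation has no detectable period",
         call. = FALSE)
  }
  T0 <- base_est$period_h
  pars <- c("alpha_a", "alpha_h", "K_a", "K_h", "n_a", "n_h",
            "k_TL_a", "k_TL_h", "tau_m_a", "tau_m_h", "delta")
  rows <- lapply(pars, function(pn) {
    p <- params; proto <- protocol
    if (pn == "delta") {
      R_new <- 1 - exp(-p$delta * fac * proto$t_int * 60)
      proto <- reactor_protocol(R = R_new, n_cycles = proto$n_cycles,
                                t_int = proto$t_int)
    } else {
      p[[pn]] <- p[[pn]] * fac
    }
    est <- tryCatch(acf_period(run_reactor(p, proto, ...), channel = channel),
                    error = function(e) NULL)
    Tp <- if (!is.null(est) && est$ok) est$period_h else NA_real_
    data.frame(parameter = pn, T_baseline_h = T0, T_perturbed_h = Tp,
               delta_T_h = Tp - T0, rel_delta_T = (Tp - T0) / T0)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
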