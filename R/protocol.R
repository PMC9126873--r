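#' Semi-continuous reactor operation protocol
#'
#' Describes the reactor's feed program: every `t_int` minutes a fraction `R`
#' of the reactor volume is replaced with fresh reagents (a "dilution cycle"),
#' and every `k`-th cycle the feed additionally carries the zeitgeber input
#' (exogenous TetR or inducer) at amplitude `A_in`, producing a periodic
#' input signal of period `T_in = k * t_int` that rises instantly and decays
#' exponentially with the dilution rate. A reference-dye amount `ref_spike`
#' may be co-fed on input cycles to monitor the realized refresh ratio.
#'
#' @param R refresh ratio, in (0, 1).
#' @param n_cycles number of dilution cycles to run (>= 1).
#' @param t_int feed interval (min); default 15.
#' @param input_species `"none"`, `"repressor"` (exogenous TetR) or
#'   `"inducer"` (aTc-like, sequesters intrinsic TetR).
#' @param A_in input amplitude added to the reactor on input cycles (nM).
#' @param k input applied every `k`-th cycle; default 16 (`T_in` = 4 h at the
#'   default `t_int`).
#' @param ref_spike reference-dye amount added on spiked cycles (a.u.).
#' @param ref_cadence `"input_cycles"` (default: dye co-fed with the
#'   zeitgeber every `k`-th cycle) or `"every_cycle"` (calibration-style
#'   traces).
#' @return An object of class `reactor_protocol` with derived fields
#'   `T_in_h` (input period, h), `delta` (1/s) and `lambda` (dimensionless
#'   bifurcation parameter).
#' @export
#' @examples
#' reactor_protocol(R = lambda_to_refresh(1.2, 16), n_cycles = 1012,
#'                  input_species = "repressor", A_in = 50)
reactor_protocol <- function(R, n_cycles, t_int = 15,
                             input_species = c("none", "repressor", "inducer"),
                             A_in = 0, k = 16, ref_spike = 0,
                             ref_cadence = c("input_cycles", "every_cycle")) {
  input_species <- match.arg(input_species)
  ref_cadence <- match.arg(ref_cadence)
  if (!is.finite(R) || R <= 0 || R >= 1) stop("reactor_protocol: R must be in (0, 1)", call. = FALSE)
  if (!is.finite(n_cycles) || n_cycles < 1) stop("reactor_protocol: n_cycles must be >= 1", call. = FALSE)
  if (!is.finite(k) || k < 1 || k != round(k)) stop("reactor_protocol: k must be a positive integer", call. = FALSE)
  if (A_in < 0 || ref_spike < 0) stop("reactor_protocol: A_in and ref_spike must be >= 0", call. = FALSE)
  p <- list(t_int = t_int, R = R, n_cycles = as.integer(n_cycles),
            input_species = input_species, A_in = A_in, k = as.integer(k),
            ref_spike = ref_spike, ref_cadence = ref_cadence,
            T_in_h = k * t_int / 60,
            delta = dilution_rate(R, t_int),
            lambda = lambda_parameter(R, k))
  class(p) <- "reactor_protocol"
  p
}

#' Protocol realizing a requested bifurcation parameter
#'
#' Convenience wrapper choosing the refresh ratio so that the bifurcation
#' parameter equals `lambda` at fixed `k` (the forcing period is quantized in
#' units of the feed interval, so scans vary the intrinsic period through `R`
#' instead).
#'
#' @param lambda requested bifurcation parameter (> 0).
#' @param n_cycles number of dilution cycles.
#' @param A_in input amplitude (nM); default 50.
#' @param k,t_int forcing cadence and feed interval; defaults 16 and 15 min
#'   (`T_in` = 4 h).
#' @param input_species forcing species; default `"repressor"`.
#' @param ref_spike reference-dye spike (a.u.).
#' @return A `reactor_protocol`.
#' @export
forced_protocol <- function(lambda, n_cycles, A_in = 50, k = 16, t_int = 15,
                            input_species = "repressor", ref_spike = 0) {
  reactor_protocol(R = lambda_to_refresh(lambda, k), n_cycles = n_cycles,
                   t_int = t_int, input_species = input_species, A_in = A_in,
                   k = k, ref_spike = ref_spike)
}

#' @export
print.reactor_protocol <- function(x, ...) {
  cat(sprintf("Reactor protocol: R = %.4f every %g min, %d cycles (%.3g h)\n",
              x$R, x$t_int, x$n_cycles, x$n_cycles * x$t_int / 60))
  cat(sprintf("  delta = %.4g 1/s, lambda = %.4g\n", x$delta, x$lambda))
  if (x$input_species == "none") {
    cat("  no zeitgeber input\n")
  } else {
    cat(sprintf("  input: %s, A_in = %g nM every %d cycles (T_in = %g h)\n",
                x$input_species, x$A_in, x$k, x$T_in_h))
  }
  invisible(x)
}

#' Discrete dilution/feed map of one cycle transition
#'
#' Every channel is mapped `x -> x * (1 - R) + feed_x`: a fraction `R` of the
#' volume is replaced and the feed contributes its payload. DNA templates are
#' not tracked explicitly — fresh templates arrive with every feed, which is
#' why the transcription rates are constants.
#'
#' @param state a [circuit_state] (or numeric vector in channel order).
#' @param R refresh ratio, in (0, 1).
#' @param feed feed payload per channel; scalar 0 or a vector matching the
#'   state. Must be non-negative.
#' @return The post-transition [circuit_state].
#' @export
#' @examples
#' apply_dilution(circuit_state(x_in = 100), R = 0.2)        # x_in -> 80
apply_dilution <- function(state, R, feed = 0) {
  if (!is.finite(R) || R <= 0 || R >= 1) stop("apply_dilution: R must be in (0, 1)", call. = FALSE)
  if (any(feed < 0)) stop("apply_dilution: negative feed", call. = FALSE)
  if (length(feed) == 1) feed <- rep(feed, length(state))
  stopifnot(length(feed) == length(state))
  as_circuit_state(as.numeric(state) * (1 - R) + as.numeric(feed))
}

#' Per-cycle feed payloads implied by a protocol
#'
#' Cycle `i` (0-based) receives the input amplitude `A_in` in the `x_in`
#' channel iff `i mod k == 0`, and the reference-dye spike on the same
#' cycles; all other feed entries are zero. With `input_species = "none"` all
#' payloads are zero regardless of `A_in`.
#'
#' @param protocol a [reactor_protocol].
#' @return A data.frame with one row per cycle: `cycle` (0-based), `x_in`,
#'   `ref`.
#' @export
input_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "reactor_protocol"))
  cycle <- seq_len(protocol$n_cycles) - 1L
  spiked <- (cycle %% protocol$k) == 0L
  x_in <- if (protocol$input_species == "none") {
    rep(0, length(cycle))
  } else {
    ifelse(spiked, protocol$A_in, 0)
  }
  ref <- if (identical(protocol$ref_cadence, "every_cycle")) {
    rep(protocol$ref_spike, length(cycle))
  } else {
    ifelse(spiked, protocol$ref_spike, 0)
  }
  data.frame(cycle = cycle, x_in = x_in, ref = ref)
}
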