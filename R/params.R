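#' Kinetic and regulatory parameters of the oscillator circuit
#'
#' Bundles all rate constants of the activator--repressor negative-feedback
#' loop together with the dilution rate. Arguments are given in the units
#' customarily quoted for cell-free expression systems (transcription rates in
#' pM/s, mRNA lifetimes in minutes); internally everything is stored in a
#' single consistent unit system (nM for concentrations, seconds for time) to
#' avoid silent unit mistakes.
#'
#' The circuit couples a sigma-factor activator `a` and the TetR repressor
#' `h`: `a` activates transcription of the repressor mRNA `r_h` through an
#' activating Hill function with threshold `K_a` and coefficient `n_a`, while
#' `h` represses transcription of the activator mRNA `r_a` through a
#' repressing Hill function with threshold `K_h` and coefficient `n_h`.
#'
#' @param alpha_a,alpha_h maximal transcription rates (pM/s).
#' @param K_a,K_h Hill threshold constants (nM).
#' @param n_a,n_h Hill coefficients (dimensionless).
#' @param k_TL_a,k_TL_h translation rates (1/s).
#' @param tau_m_a,tau_m_h mRNA lifetimes (min).
#' @param delta dilution rate (1/s).
#'
#' @return An object of class `oscillator_params`: a named list with fields
#'   `alpha_a`, `alpha_h` (nM/s), `K_a`, `K_h` (nM), `n_a`, `n_h`,
#'   `k_TL_a`, `k_TL_h` (1/s), `tau_m_a`, `tau_m_h` (s), `delta` (1/s).
#' @seealso [uniform_oscillator_params()], [preset_free_oscillator()],
#'   [preset_forced_oscillator()]
#' @export
#' @examples
#' p <- oscillator_params(alpha_a = 3, alpha_h = 3, K_a = 20, K_h = 2,
#'                        n_a = 3, n_h = 3, k_TL_a = 0.02, k_TL_h = 0.02,
#'                        tau_m_a = 12, tau_m_h = 12,
#'                        delta = dilution_rate(0.25, 15))
#' p
oscillator_params <- function(alpha_a, alpha_h, K_a, K_h, n_a, n_h,
                              k_TL_a, k_TL_h, tau_m_a, tau_m_h, delta) {
  vals <- c(alpha_a = alpha_a, alpha_h = alpha_h, K_a = K_a, K_h = K_h,
            n_a = n_a, n_h = n_h, k_TL_a = k_TL_a, k_TL_h = k_TL_h,
            tau_m_a = tau_m_a, tau_m_h = tau_m_h, delta = delta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("oscillator_params: all fields must be strictly positive; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  p <- list(
    alpha_a = alpha_a * 1e-3,  # pM/s -> nM/s
    alpha_h = alpha_h * 1e-3,
    K_a = K_a, K_h = K_h, n_a = n_a, n_h = n_h,
    k_TL_a = k_TL_a, k_TL_h = k_TL_h,
    tau_m_a = tau_m_a * 60,    # min -> s
    tau_m_h = tau_m_h * 60,
    delta = delta
  )
  class(p) <- "oscillator_params"
  p
}

#' Uniform-parameter constructor
#'
#' Constructs an [oscillator_params] object under the symmetry assumption that
#' activator and repressor branches share the same transcription rate,
#' Hill coefficient, translation rate and mRNA lifetime; only the two Hill
#' thresholds remain distinct. This is the standard simplification used when
#' analysing the circuit's qualitative dynamics.
#'
#' @param alpha shared transcription rate (pM/s).
#' @param K_a,K_h Hill thresholds (nM).
#' @param n shared Hill coefficient.
#' @param k_TL shared translation rate (1/s).
#' @param tau_m shared mRNA lifetime (min).
#' @param delta dilution rate (1/s).
#' @return An `oscillator_params` object.
#' @export
uniform_oscillator_params <- function(alpha, K_a, K_h, n, k_TL, tau_m, delta) {
  oscillator_params(alpha_a = alpha, alpha_h = alpha, K_a = K_a, K_h = K_h,
                    n_a = n, n_h = n, k_TL_a = k_TL, k_TL_h = k_TL,
                    tau_m_a = tau_m, tau_m_h = tau_m, delta = delta)
}

#' Parameter preset for the free-running oscillator
#'
#' System parameters used throughout the free-oscillator analyses:
#' `n = 3`, `K_a = 20` nM, `K_h = 2` nM, `k_TL = 0.02` 1/s, `tau_m = 12` min.
#' The transcription rate `alpha` is the main tunable (proportional to the
#' circuit DNA template concentration, realistic range roughly 0.3--3 pM/s);
#' the dilution rate is derived from the reactor's refresh ratio.
#'
#' @param alpha transcription rate (pM/s); default 3.
#' @param R refresh ratio used to derive the dilution rate; default 0.25.
#' @param t_int feed interval (min); default 15.
#' @return An `oscillator_params` object.
#' @export
preset_free_oscillator <- function(alpha = 3, R = 0.25, t_int = 15) {
  uniform_oscillator_params(alpha = alpha, K_a = 20, K_h = 2, n = 3,
                            k_TL = 0.02, tau_m = 12,
                            delta = dilution_rate(R, t_int))
}

#' Parameter preset for the forced oscillator
#'
#' System parameters used for the forced (zeitgeber-driven) analyses and the
#' bifurcation scans: as [preset_free_oscillator()] but with `alpha = 5` pM/s
#' and `n = 4`. The companion protocol applies a TetR input of amplitude
#' 50 nM every 16th feed cycle (input period 4 h at a 15 min feed interval).
#'
#' @param n Hill coefficient; default 4 (raise to probe chaotic regimes).
#' @param R refresh ratio used to derive the dilution rate; default chosen so
#'   the bifurcation parameter is `lambda = 1.2` at `k = 16`.
#' @param t_int feed interval (min); default 15.
#' @return An `oscillator_params` object.
#' @export
preset_forced_oscillator <- function(n = 4, R = lambda_to_refresh(1.2, 16),
                                     t_int = 15) {
  uniform_oscillator_params(alpha = 5, K_a = 20, K_h = 2, n = n,
                            k_TL = 0.02, tau_m = 12,
                            delta = dilution_rate(R, t_int))
}

#' Replace the dilution rate of a parameter set
#'
#' @param params an `oscillator_params` object.
#' @param delta new dilution rate (1/s).
#' @return The modified `oscillator_params` object.
#' @export
set_dilution <- function(params, delta) {
  stopifnot(inherits(params, "oscillator_params"))
  if (!is.finite(delta) || delta <= 0) stop("delta must be strictly positive")
  params$delta <- delta
  params
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("Oscillator parameters (internal units: nM, s)\n")
  cat(sprintf("  transcription  alpha_a = %.4g, alpha_h = %.4g nM/s (%.3g, %.3g pM/s)\n",
              x$alpha_a, x$alpha_h, x$alpha_a * 1e3, x$alpha_h * 1e3))
  cat(sprintf("  Hill           K_a = %.4g nM (n_a = %.3g), K_h = %.4g nM (n_h = %.3g)\n",
              x$K_a, x$n_a, x$K_h, x$n_h))
  cat(sprintf("  translation    k_TL_a = %.4g, k_TL_h = %.4g 1/s\n",
              x$k_TL_a, x$k_TL_h))
  cat(sprintf("  mRNA lifetime  tau_m_a = %.4g, tau_m_h = %.4g s (%.3g, %.3g min)\n",
              x$tau_m_a, x$tau_m_h, x$tau_m_a / 60, x$tau_m_h / 60))
  cat(sprintf("  dilution       delta = %.4g 1/s (period scale pi/delta = %.3g h)\n",
              x$delta, pi / x$delta / 3600))
  invisible(x)
}

#' Read / write a parameter set as a flat key-value config
#'
#' Serializes the constructor arguments (lab units: pM/s, nM, 1/s, min) as a
#' flat YAML or JSON mapping, chosen by file extension. `read_params()`
#' round-trips anything written by `write_params()`.
#'
#' @param params an `oscillator_params` object.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_params()` returns an `oscillator_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "oscillator_params"))
  flat <- list(
    alpha_a = params$alpha_a * 1e3, alpha_h = params$alpha_h * 1e3,
    K_a = params$K_a, K_h = params$K_h, n_a = params$n_a, n_h = params$n_h,
    k_TL_a = params$k_TL_a, k_TL_h = params$k_TL_h,
    tau_m_a = params$tau_m_a / 60, tau_m_h = params$tau_m_h / 60,
    delta = params$delta
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(flat, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension (use .yaml/.yml/.json): ", path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  flat <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension (use .yaml/.yml/.json): ", path)
  }
  need <- c("alpha_a", "alpha_h", "K_a", "K_h", "n_a", "n_h",
            "k_TL_a", "k_TL_h", "tau_m_a", "tau_m_h", "delta")
  missing <- setdiff(need, names(flat))
  if (length(missing)) {
    stop("config is missing fields: ", paste(missing, collapse = ", "))
  }
  do.call(oscillator_params, flat[need])
}
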