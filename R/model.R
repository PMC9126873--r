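#' Hill transfer functions of the two promoters
#'
#' `hill_repression()` is the fractional activity of a promoter repressed by
#' `h_eff`: `1 / (1 + (h_eff/K_h)^n_h)`, equal to 1 with no repressor and to
#' 1/2 at `h_eff = K_h`. `hill_activation()` is the fractional activity of a
#' promoter activated by `a`: `1 / (1 + (K_a/a)^n_a)`, defined by its limit 0
#' at `a = 0` (an empty reactor produces no repressor mRNA) and equal to 1/2
#' at `a = K_a`. Both are bounded in \[0, 1\] and monotone in the regulator.
#'
#' @param h_eff effective repressor concentration (nM), `>= 0`; for the forced
#'   circuit this is endogenous TetR plus any exogenously added TetR.
#' @param a activator concentration (nM), `>= 0`.
#' @param K_h,K_a Hill thresholds (nM), `> 0`.
#' @param n_h,n_a Hill coefficients, `> 0`.
#' @return Fractional promoter activity, vectorized over the regulator.
#' @export
#' @examples
#' hill_repression(2, K_h = 2, n_h = 2)   # 0.5 at threshold
#' hill_activation(0, K_a = 20, n_a = 3)  # 0 in the empty reactor
hill_repression <- function(h_eff, K_h, n_h) {
  if (!is.finite(K_h) || K_h <= 0 || !is.finite(n_h) || n_h <= 0) {
    stop("hill_repression: K_h and n_h must be strictly positive", call. = FALSE)
  }
  if (any(h_eff < 0)) stop("hill_repression: h_eff must be non-negative", call. = FALSE)
  1 / (1 + (h_eff / K_h)^n_h)
}

#' @rdname hill_repression
#' @export
hill_activation <- function(a, K_a, n_a) {
  if (!is.finite(K_a) || K_a <= 0 || !is.finite(n_a) || n_a <= 0) {
    stop("hill_activation: K_a and n_a must be strictly positive", call. = FALSE)
  }
  if (any(a < 0)) stop("hill_activation: a must be non-negative", call. = FALSE)
  # (K_a/a)^n_a overflows at a = 0; the limit of the activity there is 0
  out <- numeric(length(a))
  pos <- a > 0
  out[pos] <- 1 / (1 + (K_a / a[pos])^n_a)
  out
}

#' Right-hand side of the oscillator ODEs
#'
#' Time derivatives (per second) of the full circuit state. The core
#' four-variable model is
#' \deqn{\dot r_a = \alpha_a \frac{1}{1+(h_{eff}/K_h)^{n_h}} - (\delta + 1/\tau_{m,a})\, r_a}
#' \deqn{\dot a   = k_{TL,a}\, r_a - \delta\, a}
#' \deqn{\dot r_h = \alpha_h \frac{1}{1+(K_a/a)^{n_a}} - (\delta + 1/\tau_{m,h})\, r_h}
#' \deqn{\dot h   = k_{TL,h}\, r_h - \delta\, h}
#' The reporter proteins follow the translation/dilution dynamics of their
#' driving mRNAs (same `k_TL`), and the exogenous input `x_in` and reference
#' dye `ref` are only diluted. The forcing mode selects the effective
#' repressor concentration seen by the repressible promoter:
#' `h` (`"none"`), `h + x_in` for exogenously added repressor
#' (`"repressor"`), or `max(h - x_in, 0)` for an inducer that sequesters
#' intrinsic TetR 1:1 (`"inducer"`).
#'
#' @param state a [circuit_state] (or named numeric vector in its channel
#'   order), non-negative.
#' @param params an [oscillator_params] object.
#' @param forcing_mode one of `"none"`, `"repressor"`, `"inducer"`.
#' @param delta_override optional dilution rate (1/s) replacing
#'   `params$delta`; the reactor simulator integrates intervals with the
#'   dilution terms removed (`delta_override = 0`) because dilution is applied
#'   by the discrete feed map.
#' @return Named numeric vector of derivatives (nM/s), same channels as the
#'   state.
#' @export
ode_rhs <- function(state, params,
                    forcing_mode = c("none", "repressor", "inducer"),
                    delta_override = NULL) {
  forcing_mode <- match.arg(forcing_mode)
  stopifnot(inherits(params, "oscillator_params"))
  if (any(state < 0)) stop("ode_rhs: negative state component", call. = FALSE)
  rhs_core(as.numeric(state), params, forcing_mode,
           if (is.null(delta_override)) params$delta else delta_override)
}

# Derivative kernel without input validation. Stiff integrators probe
# slightly negative states between accepted steps; the Hill terms clamp the
# regulator arguments at zero so those probes stay finite.
rhs_core <- function(s, params, forcing_mode, delta) {
  h_eff <- switch(forcing_mode,
                  none      = max(s[4L], 0),
                  repressor = max(s[4L], 0) + max(s[7L], 0),
                  inducer   = max(s[4L] - s[7L], 0))
  rep_act <- 1 / (1 + (h_eff / params$K_h)^params$n_h)
  act     <- if (s[2L] <= 0) 0 else 1 / (1 + (params$K_a / s[2L])^params$n_a)
  d <- c(
    r_a   = params$alpha_a * rep_act - (delta + 1 / params$tau_m_a) * s[1L],
    a     = params$k_TL_a * s[1L] - delta * s[2L],
    r_h   = params$alpha_h * act - (delta + 1 / params$tau_m_h) * s[3L],
    h     = params$k_TL_h * s[3L] - delta * s[4L],
    rep_a = params$k_TL_a * s[1L] - delta * s[5L],
    rep_h = params$k_TL_h * s[3L] - delta * s[6L],
    x_in  = -delta * s[7L],
    ref   = -delta * s[8L]
  )
  d
}

#' Dilution rate of the semi-continuous reactor
#'
#' Replacing a fraction `R` of the reactor volume every `t_int` minutes is
#' equivalent, at the sampling times, to a continuous first-order dilution
#' with rate `delta = -ln(1 - R) / t_int`.
#'
#' @param R refresh ratio, in (0, 1).
#' @param t_int feed interval (min); default 15.
#' @return Dilution rate (1/s), strictly increasing in `R`.
#' @export
#' @examples
#' dilution_rate(0.25, 15)   # ~3.2e-4 1/s
dilution_rate <- function(R, t_int = 15) {
  if (any(!is.finite(R)) || any(R <= 0) || any(R >= 1)) {
    stop("dilution_rate: R must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.finite(t_int) || t_int <= 0) stop("dilution_rate: t_int must be > 0", call. = FALSE)
  -log(1 - R) / (t_int * 60)
}

#' Bifurcation parameter of the forced oscillator
#'
#' The dimensionless ratio of forcing period to intrinsic period,
#' `lambda = T_in / T ~ delta * T_in / pi = k * (-ln(1 - R)) / pi`, where the
#' input is applied every `k`-th feed cycle. `lambda_to_refresh()` inverts the
#' relation, returning the refresh ratio that realizes a requested `lambda`
#' at fixed `k`.
#'
#' @param R refresh ratio, in (0, 1).
#' @param k input applied every `k`-th feed cycle (positive integer).
#' @param lambda requested bifurcation parameter (> 0).
#' @return `lambda_parameter()`: the dimensionless bifurcation parameter;
#'   `lambda_to_refresh()`: the corresponding refresh ratio.
#' @export
#' @examples
#' lambda_parameter(0.25, 16)            # ~1.465
#' lambda_to_refresh(1.2, 16)            # ~0.21
lambda_parameter <- function(R, k) {
  if (any(!is.finite(R)) || any(R <= 0) || any(R >= 1)) {
    stop("lambda_parameter: R must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.finite(k) || k < 1) stop("lambda_parameter: k must be >= 1", call. = FALSE)
  k * (-log(1 - R)) / pi
}

#' @rdname lambda_parameter
#' @export
lambda_to_refresh <- function(lambda, k) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("lambda_to_refresh: lambda must be > 0", call. = FALSE)
  }
  if (!is.finite(k) || k < 1) stop("lambda_to_refresh: k must be >= 1", call. = FALSE)
  1 - exp(-pi * lambda / k)
}

#' Predicted free-running period from the dilution rate
#'
#' The intrinsic period of the oscillator is set almost entirely by the
#' dilution rate, `T ~ C * pi / delta` with `C` close to 1.
#'
#' @param delta dilution rate (1/s).
#' @param C dimensionless proportionality constant; default 1.
#' @return Period in hours.
#' @export
predicted_period <- function(delta, C = 1) {
  if (any(!is.finite(delta)) || any(delta <= 0)) stop("predicted_period: delta must be > 0", call. = FALSE)
  if (!is.finite(C) || C <= 0) stop("predicted_period: C must be > 0", call. = FALSE)
  C * pi / delta / 3600
}

#' Nullclines of the protein subsystem
#'
#' In the quasi-steady-state limit for the mRNAs (`delta << 1/tau_m`) the
#' protein nullclines are
#' `a(h) = (alpha_a/delta) * k_TL_a * tau_m_a / (1 + (h/K_h)^n_h)` and
#' `h(a) = (alpha_h/delta) * k_TL_h * tau_m_h / (1 + (K_a/a)^n_a)`.
#' The system parameters set the shape of these transfer curves; the control
#' parameters `alpha` and `delta` set their scale.
#'
#' @param params an [oscillator_params] object.
#' @param h_grid repressor concentrations (nM) at which to evaluate `a(h)`.
#' @param a_grid activator concentrations (nM) at which to evaluate `h(a)`.
#' @return A list with data.frames `a_of_h` (`h`, `a`) and `h_of_a`
#'   (`a`, `h`), both in nM.
#' @export
nullclines <- function(params, h_grid, a_grid) {
  stopifnot(inherits(params, "oscillator_params"))
  if (length(h_grid) == 0 || length(a_grid) == 0) {
    stop("nullclines: empty grid", call. = FALSE)
  }
  scale_a <- params$alpha_a / params$delta * params$k_TL_a * params$tau_m_a
  scale_h <- params$alpha_h / params$delta * params$k_TL_h * params$tau_m_h
  list(
    a_of_h = data.frame(h = h_grid,
                        a = scale_a * hill_repression(h_grid, params$K_h, params$n_h)),
    h_of_a = data.frame(a = a_grid,
                        h = scale_h * hill_activation(a_grid, params$K_a, params$n_a))
  )
}

#' Fixed point of the protein nullclines
#'
#' Locates the intersection of the two nullclines by one-dimensional
#' root-finding on the composed map `h -> h(a(h)) - h`, which is monotone
#' decreasing minus identity and therefore has a unique zero. The result is
#' the (quasi-steady-state) equilibrium the damped regimes relax towards.
#'
#' @param params an [oscillator_params] object.
#' @param tol root-finder tolerance (nM); default 1e-10.
#' @return A [circuit_state] with the equilibrium protein concentrations `a`
#'   and `h` (and the consistent quasi-steady-state mRNA levels).
#' @export
fixed_point <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "oscillator_params"))
  scale_a <- params$alpha_a / params$delta * params$k_TL_a * params$tau_m_a
  scale_h <- params$alpha_h / params$delta * params$k_TL_h * params$tau_m_h
  g <- function(h) {
    a <- scale_a * hill_repression(h, params$K_h, params$n_h)
    scale_h * hill_activation(a, params$K_a, params$n_a) - h
  }
  upper <- scale_h * 1.0001 + tol
  if (g(0) < 0 || g(upper) > 0) {
    stop("fixed_point: no sign change on the search bracket", call. = FALSE)
  }
  h_star <- stats::uniroot(g, c(0, upper), tol = tol)$root
  a_star <- scale_a * hill_repression(h_star, params$K_h, params$n_h)
  circuit_state(
    r_a = a_star * params$delta / params$k_TL_a,
    a = a_star,
    r_h = h_star * params$delta / params$k_TL_h,
    h = h_star,
    rep_a = a_star, rep_h = h_star
  )
}
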