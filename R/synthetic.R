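#' Measurement-noise model for synthetic recordings
#'
#' Noise is applied in intensity space, where the instrument actually
#' measures: first a multiplicative lognormal factor with unit mean and
#' coefficient of variation `cv_mult` on the background-subtracted signal
#' (illumination and volume variability; the background ROI is subtracted
#' frame by frame, so common-mode gain cancels out of `I - B`), then
#' additive Gaussian noise with standard deviation `sigma_add` on top of
#' the constant background level. Identical seeds give bit-identical
#' datasets.
#'
#' @param cv_mult coefficient of variation of the multiplicative component;
#'   default 0.05.
#' @param sigma_add standard deviation of the additive component (a.u.);
#'   default 0.
#' @param background_level constant background offset (a.u.); default 0.
#' @param seed integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv_mult = 0.05, sigma_add = 0, background_level = 0,
                        seed = 1L) {
  if (cv_mult < 0 || sigma_add < 0) stop("noise_model: negative noise scale", call. = FALSE)
  nm <- list(cv_mult = cv_mult, sigma_add = sigma_add,
             background_level = background_level, seed = as.integer(seed))
  class(nm) <- "noise_model"
  nm
}

apply_noise <- function(x, noise) {
  if (noise$cv_mult > 0) {
    sdlog <- sqrt(log(1 + noise$cv_mult^2))
    x <- x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  x + noise$background_level +
    if (noise$sigma_add > 0) stats::rnorm(length(x), 0, noise$sigma_add) else 0
}

#' Late-run fatigue of the reactor's refresh ratio
#'
#' Long recordings show a decline of the realized refresh ratio of about one
#' percentage point setting in after roughly 36 h, a sign of reactor
#' fatigue; the dilution rate, and with it the bifurcation parameter, drifts
#' correspondingly. Modeled as a step drop of size `drop` at `onset_h`
#' (minimal model), or as a linear ramp from `onset_h` to the end of the
#' run.
#'
#' @param onset_h fatigue onset (h); default 36.
#' @param drop absolute decrease of the refresh ratio; default 0.01
#'   (one percentage point).
#' @param shape `"step"` (default) or `"linear"`.
#' @return An object of class `fatigue_model`.
#' @export
fatigue_model <- function(onset_h = 36, drop = 0.01,
                          shape = c("step", "linear")) {
  shape <- match.arg(shape)
  if (drop < 0) stop("fatigue_model: drop must be >= 0", call. = FALSE)
  fm <- list(onset_h = onset_h, drop = drop, shape = shape)
  class(fm) <- "fatigue_model"
  fm
}

#' Per-cycle refresh ratios implied by a fatigue model
#'
#' @param fatigue a [fatigue_model()] or NULL (no fatigue).
#' @param R0 nominal refresh ratio.
#' @param n_cycles number of cycles.
#' @param t_int feed interval (min).
#' @return Numeric vector of length `n_cycles`, floored just above zero.
#' @export
fatigue_refresh_schedule <- function(fatigue, R0, n_cycles, t_int = 15) {
  if (is.null(fatigue)) return(rep(R0, n_cycles))
  stopifnot(inherits(fatigue, "fatigue_model"))
  t_h <- (seq_len(n_cycles) - 1) * t_int / 60
  dec <- if (fatigue$shape == "step") {
    ifelse(t_h >= fatigue$onset_h, fatigue$drop, 0)
  } else {
    ramp_span <- max(max(t_h) - fatigue$onset_h, t_int / 60)
    pmin(pmax((t_h - fatigue$onset_h) / ramp_span, 0), 1) * fatigue$drop
  }
  pmax(R0 - dec, 1e-4)
}

#' Generate a synthetic forced-oscillator experiment
#'
#' Produces a pseudo-experimental dataset with the statistical structure of
#' a microfluidic fluorescence recording: the mechanistic reactor simulation
#' is run (with per-cycle refresh ratios from the fatigue model, if any),
#' the reporter and reference channels are converted to raw intensities by
#' the exact inverse of the calibrated intensity normalization, and seeded
#' multiplicative-then-additive noise is applied. The noise-free ground
#' truth is always returned alongside, so recovery of period, refresh ratio
#' and rotation number can be checked against it.
#'
#' @param params an [oscillator_params].
#' @param protocol a [reactor_protocol]; set `ref_spike > 0` to obtain a
#'   usable reference-dye channel.
#' @param noise a [noise_model()].
#' @param fatigue a [fatigue_model()] or NULL.
#' @param calibration an [intensity_calibration()].
#' @param ... passed to [run_reactor()].
#' @return An object of class `synthetic_experiment`: list with
#'   `raw` (intensity-space `time_trace`, channels `I_rep_a`, `I_rep_h`,
#'   `I_ref`), `truth` (the noise-free concentration `time_trace`),
#'   `calibration`, `noise`, `fatigue`, `protocol`, `params`.
#' @export
generate_experiment <- function(params, protocol, noise = noise_model(),
                                fatigue = NULL,
                                calibration = intensity_calibration(), ...) {
  stopifnot(inherits(noise, "noise_model"))
  R_sched <- fatigue_refresh_schedule(fatigue, protocol$R, protocol$n_cycles,
                                      protocol$t_int)
  truth <- run_reactor(params, protocol,
                       R_schedule = if (is.null(fatigue)) NULL else R_sched,
                       ...)
  set.seed(noise$seed)
  raw <- data.frame(cycle = truth$cycle, time_h = truth$time_h)
  # concentrations are tracked in nM; the calibration works in uM.
  # Multiplicative noise scales the background-subtracted signal, the
  # additive term sits on top of the background.
  noisy_intensity <- function(conc_nM) {
    s <- concentration_to_intensity(conc_nM / 1e3, calibration) - calibration$B
    calibration$B + apply_noise(s, noise)
  }
  raw$I_rep_a <- noisy_intensity(truth$rep_a)
  raw$I_rep_h <- noisy_intensity(truth$rep_h)
  raw$I_ref <- noisy_intensity(truth$ref)
  out <- list(raw = new_time_trace(raw, protocol = protocol),
              truth = truth, calibration = calibration, noise = noise,
              fatigue = fatigue, protocol = protocol, params = params)
  class(out) <- "synthetic_experiment"
  out
}

#' Recover concentration channels from a raw synthetic dataset
#'
#' Applies the calibrated intensity normalization to the raw channels of a
#' [generate_experiment()] dataset, returning a concentration-space trace
#' (nM) comparable with the ground truth. With zero noise this is the exact
#' identity.
#'
#' @param experiment a `synthetic_experiment`.
#' @return A `time_trace` with channels `rep_a`, `rep_h`, `ref` in nM.
#' @export
recover_concentrations <- function(experiment) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  raw <- experiment$raw; cal <- experiment$calibration
  df <- data.frame(cycle = raw$cycle, time_h = raw$time_h,
                   rep_a = normalize_intensity(raw$I_rep_a, cal) * 1e3,
                   rep_h = normalize_intensity(raw$I_rep_h, cal) * 1e3,
                   ref = normalize_intensity(raw$I_ref, cal) * 1e3)
  new_time_trace(df, protocol = experiment$protocol)
}

#' Generate a noisy Hill titration table
#'
#' Evaluates the requested Hill transfer curve on a concentration grid and
#' applies seeded measurement noise; the result is the table consumed by
#' [fit_hill()].
#'
#' @param mode `"repression"` or `"activation"`.
#' @param K Hill threshold (nM).
#' @param n Hill coefficient.
#' @param conc_grid regulator concentrations (nM); should span the
#'   transition around `K`.
#' @param noise a [noise_model()].
#' @return A data.frame with columns `conc_nM`, `response`.
#' @export
generate_titration <- function(mode = c("repression", "activation"), K, n,
                               conc_grid, noise = noise_model()) {
  mode <- match.arg(mode)
  stopifnot(inherits(noise, "noise_model"))
  y <- if (mode == "repression") {
    hill_repression(conc_grid, K, n)
  } else {
    hill_activation(conc_grid, K, n)
  }
  set.seed(noise$seed)
  data.frame(conc_nM = conc_grid, response = apply_noise(y, noise))
}

#' Generate a spiked, decaying reference-dye trace
#'
#' Pure tracer dynamics, computed in closed form: the dye is spiked on the
#' protocol's labeled feed cycles, diluted geometrically by the (possibly
#' fatigue-modulated) refresh ratio at every cycle transition, and measured
#' with seeded noise. The inter-spike samples of the noiseless trace are
#' exactly geometric with ratio `1 - R`.
#'
#' @param protocol a [reactor_protocol] with `ref_spike > 0`.
#' @param noise a [noise_model()] (use `cv_mult = 0` for a noiseless trace).
#' @param fatigue a [fatigue_model()] or NULL.
#' @return A single-channel `time_trace` (`cycle`, `time_h`, `ref`).
#' @export
generate_reference_trace <- function(protocol, noise = noise_model(),
                                     fatigue = NULL) {
  stopifnot(inherits(protocol, "reactor_protocol"),
            inherits(noise, "noise_model"))
  n <- protocol$n_cycles
  feeds <- input_schedule(protocol)
  R_sched <- fatigue_refresh_schedule(fatigue, protocol$R, n, protocol$t_int)
  val <- numeric(n); cur <- 0
  for (i in seq_len(n)) {
    cur <- if (i == 1) cur + feeds$ref[i] else cur * (1 - R_sched[i]) + feeds$ref[i]
    val[i] <- cur
  }
  set.seed(noise$seed)
  df <- data.frame(cycle = seq_len(n) - 1L, time_h = seq_len(n) * protocol$t_int / 60,
                   ref = apply_noise(val, noise))
  new_time_trace(df, protocol = protocol)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the file layout expected by downstream tooling: `trace_raw.csv`,
#' `trace_truth.csv`, `reference.csv` (the raw reference channel),
#' `calibration.json` and `manifest.json` (all parameters plus the noise
#' seed, sufficient to regenerate the dataset exactly).
#'
#' @param experiment a `synthetic_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trace(experiment$raw, file.path(dir, "trace_raw.csv"))
  write_trace(experiment$truth, file.path(dir, "trace_truth.csv"))
  ref <- experiment$raw[, c("cycle", "time_h", "I_ref")]
  utils::write.csv(ref, file.path(dir, "reference.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(experiment$calibration),
                       file.path(dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  p <- experiment$params; proto <- experiment$protocol
  manifest <- list(
    params = list(alpha_a_pM_s = p$alpha_a * 1e3, alpha_h_pM_s = p$alpha_h * 1e3,
                  K_a_nM = p$K_a, K_h_nM = p$K_h, n_a = p$n_a, n_h = p$n_h,
                  k_TL_a = p$k_TL_a, k_TL_h = p$k_TL_h,
                  tau_m_a_min = p$tau_m_a / 60, tau_m_h_min = p$tau_m_h / 60,
                  delta = p$delta),
    protocol = unclass(proto),
    noise = unclass(experiment$noise),
    fatigue = if (is.null(experiment$fatigue)) NULL else unclass(experiment$fatigue)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
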