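test_that("ACF period recovers known periodicities", {
  t_h <- seq(0, 24, by = 0.25)
  x <- cos(2 * pi * t_h / 3)
  est <- acf_period(x, dt_h = 0.25)
  expect_true(est$ok)
  expect_equal(est$period_h, 3, tolerance = 0.01)
  expect_equal(est$uncertainty_h, est$period_h / est$n_maxima_used)

  # robust to 5% multiplicative noise
  set.seed(42)
  xn <- x * (1 + 0.05 * rnorm(length(x)))
  estn <- acf_period(xn, dt_h = 0.25)
  expect_equal(estn$period_h, 3, tolerance = 0.15)

  # invariant under affine transforms of the signal
  est2 <- acf_period(5 - 3 * x, dt_h = 0.25)
  expect_equal(est2$period_h, est$period_h)

  # monotone decay: a no-period result, not an error
  est3 <- acf_period(exp(-seq(0, 24, by = 0.25)), dt_h = 0.25)
  expect_false(est3$ok)
  expect_true(is.na(est3$period_h))
})

test_that("damped-cosine fit agrees with the ACF estimator", {
  t_h <- seq(0, 48, by = 0.25)
  x <- exp(-t_h / 20) * cos(2 * pi * t_h / 3.5)
  est <- damped_cosine_period(x, dt_h = 0.25)
  expect_true(est$ok)
  expect_equal(est$period_h, 3.5, tolerance = 0.05)

  # both estimators agree on a simulated oscillator trace
  p <- preset_free_oscillator(alpha = 3, R = 0.25)
  tr <- run_reactor(p, reactor_protocol(R = 0.25, n_cycles = 192))
  e_acf <- acf_period(tr, channel = "rep_a")
  e_cos <- damped_cosine_period(tr, channel = "rep_a", exclude_initial_h = 1)
  expect_lt(abs(e_cos$period_h - e_acf$period_h), e_acf$uncertainty_h)

  # pure exponential decay is flagged, not silently fitted
  est_exp <- tryCatch(damped_cosine_period(exp(-t_h / 5), dt_h = 0.25),
                      error = function(e) e)
  expect_true(inherits(est_exp, "error") ||
                (!est_exp$ok && grepl("decay", est_exp$reason)))
})

test_that("phase metrics separate sustained, damped and overdamped regimes", {
  t_h <- seq(0, 48, by = 0.25)
  # constant-amplitude oscillation
  pm <- phase_metrics(2 + sin(2 * pi * t_h / 4), dt_h = 0.25)
  expect_equal(pm$regime, "sustained")
  expect_equal(pm$gamma, 1, tolerance = 1e-6)

  # triangular peaks of heights 8, 4, 2, 1 -> mean successive ratio 2
  peak <- function(h) c(seq(0, h, length.out = 11), seq(h, 0, length.out = 11)[-1])
  x <- c(peak(8), peak(4), peak(2), peak(1))
  pm2 <- phase_metrics(x, dt_h = 0.25, exclude_initial_h = 0)
  expect_equal(pm2$gamma, 2)
  expect_equal(pm2$regime, "damped")

  # monotone equilibration: overdamped with a fitted time constant
  pm3 <- phase_metrics(10 * (1 - exp(-t_h / 6)), dt_h = 0.25)
  expect_equal(pm3$regime, "overdamped")
  expect_equal(pm3$tau_eq_h, 6, tolerance = 0.05)

  # flat trace: overdamped with undefined time constant
  pm4 <- phase_metrics(rep(1, 100), dt_h = 0.25)
  expect_equal(pm4$regime, "overdamped")
  expect_true(is.na(pm4$tau_eq_h))
})

test_that("higher expression strength and dilution favor sustained oscillation", {
  grid <- expand.grid(alpha = c(0.3, 3), R = c(0.1, 0.3))
  rank <- c(overdamped = 0, damped = 1, sustained = 2)
  regimes <- vapply(seq_len(nrow(grid)), function(i) {
    p <- preset_free_oscillator(alpha = grid$alpha[i], R = grid$R[i])
    tr <- run_reactor(p, reactor_protocol(R = grid$R[i], n_cycles = 192))
    phase_metrics(tr, channel = "rep_a")$regime
  }, character(1))
  r <- matrix(rank[regimes], 2, 2)  # rows: alpha, cols: R
  expect_gte(r[2, 2], r[1, 2])  # more alpha at high R
  expect_gte(r[2, 2], r[2, 1])  # more dilution at high alpha
  expect_gt(r[2, 2], r[1, 1])   # both together move towards sustained
  expect_equal(r[2, 2], 2)      # strongest corner is sustained
})

test_that("return map represents m-cycles as m distinct points", {
  expect_equal(nrow(unique(return_map(rep(5, 6)))), 1)
  rm2 <- return_map(rep(c(3, 7), 5))
  expect_equal(nrow(unique(rm2)), 2)
  expect_error(return_map(5), "at least 2")
})

test_that("instantaneous refresh ratio reads a decaying reference trace", {
  I <- 100 * 0.8^(0:10)
  rs <- instantaneous_refresh(I, dt_h = 0.25, frac_threshold = 0.0001)
  expect_true(all(abs(rs$R_t - 0.2) < 1e-12))
  # low-intensity points fall off the mask
  rs2 <- instantaneous_refresh(I, dt_h = 0.25, frac_threshold = 0.3)
  expect_equal(sum(rs2$mask), sum(I[-length(I)] > 0.3 * max(I)))
  # pairs spanning a feed spike are reported, flagged, excluded from summary
  I_sp <- c(100 * 0.8^(0:5), 100 * 0.8^(0:5))
  rs3 <- instantaneous_refresh(I_sp, dt_h = 0.25, frac_threshold = 0.0001)
  spike_pair <- which(diff(I_sp) > 0)
  expect_true(all(rs3$flagged[spike_pair]))
  expect_equal(mean_refresh(rs3, 0, 10), 0.2, tolerance = 1e-12)
})

test_that("intensity normalization is linear and exactly invertible", {
  cal <- intensity_calibration()
  # reference identity: measuring the 1 uM standard itself
  I_std <- concentration_to_intensity(1, cal)
  expect_equal(normalize_intensity(I_std, cal), 1)
  # linearity
  I1 <- concentration_to_intensity(0.4, cal)
  expect_equal(normalize_intensity(cal$B + 2 * (I1 - cal$B), cal), 0.8)
  # round trip across magnitudes
  c0 <- c(0, 1e-4, 0.03, 1, 7.5)
  expect_equal(normalize_intensity(concentration_to_intensity(c0, cal), cal), c0)
  expect_error(intensity_calibration(I0 = 5, B0 = 5), "denominator")
})

test_that("Hill transfer-curve fitting recovers parameters with honest errors", {
  conc <- c(0.2, 0.5, 1, 2, 5, 10, 20)
  resp <- hill_repression(conc, K_h = 2.2, n_h = 2.1)
  fit <- fit_hill(conc, resp, mode = "repression")
  expect_equal(fit$K, 2.2, tolerance = 1e-4)
  expect_equal(fit$n, 2.1, tolerance = 1e-4)

  conc_a <- c(20, 50, 80, 115, 160, 250, 500)
  resp_a <- hill_activation(conc_a, K_a = 115, n_a = 3.4)
  fit_a <- fit_hill(conc_a, resp_a, mode = "activation")
  expect_equal(fit_a$K, 115, tolerance = 1e-3)
  expect_equal(fit_a$n, 3.4, tolerance = 1e-3)
  expect_true(fit_a$K_ci[1] < 115 && 115 < fit_a$K_ci[2])

  expect_error(fit_hill(c(1, 2, 3), c(1, 0.5, 0.2)), "at least 4")
  # titration entirely below the threshold: unidentifiable
  conc_low <- c(0.05, 0.1, 0.15, 0.2, 0.3) * 2.2 / 10
  expect_error(fit_hill(conc_low, hill_repression(conc_low, 2.2, 2.1)),
               "unidentifiable|span|converge")
})

test_that("noisy titrations yield estimates at the experimental precision", {
  conc <- c(10, 20, 40, 70, 90, 115, 140, 180, 250, 400, 700)
  hits <- vapply(1:20, function(seed) {
    tab <- generate_titration("activation", K = 115, n = 3.4, conc,
                              noise = noise_model(cv_mult = 0.05, seed = seed))
    fit <- tryCatch(fit_hill(tab$conc_nM, tab$response, mode = "activation"),
                    error = function(e) NULL)
    !is.null(fit) && abs(fit$K - 115) < 6 && abs(fit$n - 3.4) < 0.6
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
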