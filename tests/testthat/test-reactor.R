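test_that("the dilution/feed map does plain volume-replacement arithmetic", {
  s <- circuit_state(x_in = 100)
  expect_equal(apply_dilution(s, R = 0.2)[["x_in"]], 80)
  feed <- rep(0, 8); feed[7] <- 50
  expect_equal(apply_dilution(circuit_state(), R = 0.25, feed)[["x_in"]], 50)
  # 16 dilution steps at R = 0.25 attenuate to (1-R)^16 ~ 0.01
  x <- 1
  for (i in 1:16) x <- apply_dilution(circuit_state(x_in = x), 0.25)[["x_in"]]
  expect_equal(x, 0.75^16)
  expect_equal(signif(x, 2), 0.01)
  expect_error(apply_dilution(s, R = 0.2, feed = -1), "negative")
  expect_error(apply_dilution(s, R = 1.2), "in \\(0, 1\\)")
})

test_that("the input schedule spikes every k-th cycle, starting at cycle 0", {
  proto <- reactor_protocol(R = 0.25, n_cycles = 48, input_species = "repressor",
                            A_in = 50, k = 16)
  sched <- input_schedule(proto)
  expect_equal(sched$cycle[sched$x_in > 0], c(0, 16, 32))
  expect_true(all(sched$x_in %in% c(0, 50)))

  proto1 <- reactor_protocol(R = 0.25, n_cycles = 5, input_species = "repressor",
                             A_in = 10, k = 1)
  expect_true(all(input_schedule(proto1)$x_in == 10))

  # disabled forcing zeroes the payload regardless of amplitude
  proto0 <- reactor_protocol(R = 0.25, n_cycles = 48, input_species = "none",
                             A_in = 50, k = 16)
  expect_true(all(input_schedule(proto0)$x_in == 0))

  # reference dye can be fed on every cycle for calibration traces
  protoc <- reactor_protocol(R = 0.25, n_cycles = 8, ref_spike = 5,
                             ref_cadence = "every_cycle")
  expect_true(all(input_schedule(protoc)$ref == 5))
})

test_that("protocol derives the forcing period and bifurcation parameter", {
  proto <- forced_protocol(1.2, n_cycles = 10)
  expect_equal(proto$T_in_h, 4)
  expect_equal(proto$lambda, 1.2)
  expect_equal(proto$delta, dilution_rate(proto$R, proto$t_int))
  expect_error(reactor_protocol(R = 0.25, n_cycles = 0), "n_cycles")
})

test_that("a non-reacting tracer decays exactly geometrically per cycle", {
  p <- preset_free_oscillator(alpha = 3, R = 0.25)
  tr <- run_reactor(p, reactor_protocol(R = 0.25, n_cycles = 20),
                    initial = circuit_state(x_in = 1, ref = 2))
  # samples are taken pre-dilution: cycle i has seen i transitions
  expect_equal(tr$x_in, 0.75^(0:19))
  expect_equal(tr$ref, 2 * 0.75^(0:19))
  # dilution rate in the stored params is derived from the protocol
  expect_equal(attr(tr, "params")$delta, dilution_rate(0.25, 15))
})

test_that("free-running dynamics show the expected regimes and timescale", {
  p <- preset_free_oscillator(alpha = 3, R = 0.25)
  tr <- run_reactor(p, reactor_protocol(R = 0.25, n_cycles = 288))
  est <- acf_period(tr, channel = "rep_a")
  expect_true(est$ok)
  # period close to the pi/delta scale
  expect_equal(est$period_h, predicted_period(dilution_rate(0.25)),
               tolerance = 0.15)
  # reducing transcription 10x moves the system to the damped regime
  p_low <- preset_free_oscillator(alpha = 0.3, R = 0.25)
  tr_low <- run_reactor(p_low, reactor_protocol(R = 0.25, n_cycles = 192))
  pm_low <- phase_metrics(tr_low, channel = "rep_a")
  pm_hi <- phase_metrics(tr, channel = "rep_a")
  expect_equal(pm_hi$regime, "sustained")
  expect_true(pm_low$regime %in% c("damped", "overdamped"))
})

test_that("interval-end samples converge to the continuous-dilution limit", {
  delta <- dilution_rate(0.25, 15)
  p <- preset_free_oscillator(alpha = 3, R = 0.25)
  ref <- continuous_limit_reference(p, horizon_h = 24, dt_h = 0.25)
  sup_err <- vapply(c(15, 7.5, 3.75), function(t_int) {
    R <- 1 - exp(-delta * t_int * 60)
    proto <- reactor_protocol(R = R, n_cycles = round(24 * 60 / t_int),
                              t_int = t_int)
    tr <- run_reactor(p, proto)
    # compare on the common 15-min grid
    at <- match(ref$time_h, round(tr$time_h, 10))
    max(abs(tr$rep_a[at] - ref$rep_a))
  }, numeric(1))
  expect_true(all(diff(sup_err) < 0))   # halving t_int shrinks the error
  expect_lt(sup_err[3], sup_err[1] / 3)
  # identical delta, zero feeds: identical exponential washout of a tracer
  tr_w <- continuous_limit_reference(p, horizon_h = 5, dt_h = 0.25,
                                     initial = circuit_state(ref = 1))
  expect_equal(tr_w$ref, exp(-delta * tr_w$time_h * 3600), tolerance = 1e-6)
})

test_that("results are stable under integrator tolerance tightening", {
  p <- preset_forced_oscillator()
  proto <- forced_protocol(1.2, n_cycles = 120)
  tr1 <- run_reactor(p, proto)
  tr2 <- run_reactor(p, proto, rtol = 1e-7, atol = 1e-10)
  expect_equal(tr1$h, tr2$h, tolerance = 1e-4)
})

test_that("all channels stay non-negative over long forced runs", {
  res <- forced_point_cached(1.20)
  tr <- res$trace
  expect_gte(nrow(tr), 500)
  expect_true(all(as.matrix(tr[, -(1:2)]) >= 0))
})

test_that("forced oscillators adapt to the input period within a couple of cycles", {
  res <- forced_point_cached(1.48)
  tr <- res$trace
  # skip 2 input periods (32 cycles), then the ACF period matches T_in
  post <- tr$h[tr$cycle >= 32 & tr$cycle < 224]
  est <- acf_period(post, dt_h = 0.25)
  expect_equal(est$period_h, 4, tolerance = 0.1)
})

test_that("time traces round-trip through CSV and keep absent channels absent", {
  p <- preset_free_oscillator(alpha = 3, R = 0.25)
  tr <- run_reactor(p, reactor_protocol(R = 0.25, n_cycles = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  df_in <- as.data.frame(tr); attributes(df_in)[c("params", "protocol")] <- NULL
  df_out <- as.data.frame(tr2)
  expect_equal(df_out, df_in, tolerance = 1e-12, ignore_attr = TRUE)

  sub <- tr[, c("cycle", "time_h", "h")]
  write_trace(sub, path)
  tr3 <- read_trace(path)
  expect_false("rep_a" %in% names(tr3))
  expect_error(get_channel(tr3, "rep_a"), "no channel")
})
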