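test_that("Hill transfer functions obey their identities and bounds", {
  expect_equal(hill_repression(2, K_h = 2, n_h = 3), 0.5)
  expect_equal(hill_repression(0, K_h = 2, n_h = 3), 1.0)
  expect_equal(hill_repression(4, K_h = 2, n_h = 2), 0.2)  # 1/(1+4)

  expect_equal(hill_activation(20, K_a = 20, n_a = 3), 0.5)
  expect_equal(hill_activation(0, K_a = 20, n_a = 3), 0.0)
  expect_equal(hill_activation(60, K_a = 20, n_a = 1), 0.75)  # 1/(1+1/3)

  # bounded and monotone for a spread of parameters
  for (n in c(0.5, 1, 2, 4, 8)) {
    for (K in c(0.1, 2, 115)) {
      x <- seq(0, 10 * K, length.out = 50)
      rep_v <- hill_repression(x, K, n)
      act_v <- hill_activation(x, K, n)
      expect_true(all(rep_v >= 0 & rep_v <= 1))
      expect_true(all(act_v >= 0 & act_v <= 1))
      expect_true(all(diff(rep_v) <= 1e-12))
      expect_true(all(diff(act_v) >= -1e-12))
    }
  }

  expect_error(hill_repression(1, K_h = -1, n_h = 2), "positive")
  expect_error(hill_activation(1, K_a = 2, n_a = 0), "positive")
  expect_error(hill_repression(-1, K_h = 2, n_h = 2), "non-negative")
})

test_that("dilution rate follows the refresh-ratio law", {
  # -ln(0.75)/900 s
  expect_equal(dilution_rate(0.25, 15), -log(0.75) / 900)
  expect_equal(signif(dilution_rate(0.25, 15), 4), 3.196e-4)
  # inverse identity: R = 1 - 1/e gives delta = 1/t_int
  expect_equal(dilution_rate(1 - exp(-1), 15), 1 / 900)
  # strictly increasing in R, vanishing as R -> 0+
  Rs <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(dilution_rate(Rs)) > 0))
  expect_lt(dilution_rate(1e-9), 1e-11)
  expect_error(dilution_rate(0), "inside")
  expect_error(dilution_rate(1), "inside")
  expect_error(dilution_rate(0.2, t_int = 0), "t_int")
})

test_that("bifurcation parameter and its inverse are consistent", {
  expect_equal(lambda_parameter(0.25, 16), 16 * log(4 / 3) / pi)
  expect_equal(lambda_parameter(0.25, 16), 1.4651, tolerance = 1e-4)
  # inverse round-trips
  R <- lambda_to_refresh(1.20, 16)
  expect_equal(R, 0.2099, tolerance = 1e-3)
  expect_equal(lambda_parameter(R, 16), 1.20)
  # linear in k
  expect_equal(lambda_parameter(0.3, 32), 2 * lambda_parameter(0.3, 16))
  # machine-precision consistency with the dilution rate
  for (R in c(0.05, 0.21, 0.25, 0.4, 0.9)) {
    for (k in c(1, 4, 16)) {
      expect_equal(lambda_parameter(R, k),
                   dilution_rate(R, 15) * (k * 15 * 60) / pi)
    }
  }
  expect_error(lambda_parameter(1.2, 16), "inside")
  expect_error(lambda_to_refresh(-1, 16), "lambda")
})

test_that("predicted period converts and scales correctly", {
  expect_equal(predicted_period(pi / 3600, C = 1), 1)  # delta = pi per hour
  expect_equal(predicted_period(dilution_rate(0.25, 15)), 2.7301, tolerance = 1e-4)
  d <- 3e-4
  expect_equal(predicted_period(2 * d), predicted_period(d) / 2)
})

test_that("state derivatives implement the circuit model", {
  p <- preset_free_oscillator(alpha = 3, R = 0.25)
  d0 <- ode_rhs(circuit_state(), p)
  expect_equal(d0[["r_a"]], p$alpha_a)   # empty reactor: only activator mRNA
  expect_equal(d0[["r_h"]], 0)
  expect_equal(unname(d0[c("a", "h", "rep_a", "rep_h", "x_in", "ref")]),
               rep(0, 6))

  # exogenous repressor lowers activator-mRNA production at equal h
  s1 <- circuit_state(h = 1)
  s2 <- circuit_state(h = 1, x_in = 5)
  expect_lt(ode_rhs(s2, p, forcing_mode = "repressor")[["r_a"]],
            ode_rhs(s1, p, forcing_mode = "repressor")[["r_a"]])
  # inducer sequesters repressor: more input raises production
  s3 <- circuit_state(h = 5, x_in = 5)
  expect_gt(ode_rhs(s3, p, forcing_mode = "inducer")[["r_a"]],
            ode_rhs(s1, p, forcing_mode = "inducer")[["r_a"]])
  # non-negativity: any zeroed component has a non-negative derivative
  set.seed(7)
  for (i in 1:20) {
    s <- circuit_state(r_a = runif(1, 0, 1), a = runif(1, 0, 50),
                       r_h = runif(1, 0, 1), h = runif(1, 0, 50))
    z <- sample(names(s), 3)
    s[z] <- 0
    d <- ode_rhs(s, p)
    expect_true(all(d[z] >= 0))
  }
  expect_error(ode_rhs(c(-1, 0, 0, 0, 0, 0, 0, 0), p), "negative")
})

test_that("nullclines scale with control parameters and locate the fixed point", {
  # slow dilution so the mRNA quasi-steady-state assumption holds
  p <- preset_free_oscillator(alpha = 3, R = 0.02)
  h_grid <- seq(0, 50, by = 0.5)
  a_grid <- seq(0, 500, by = 5)
  nc <- nullclines(p, h_grid, a_grid)
  # repression-free plateau
  expect_equal(nc$a_of_h$a[1], p$alpha_a / p$delta * p$k_TL_a * p$tau_m_a)
  # doubling both transcription rates doubles both curves
  p2 <- p
  p2$alpha_a <- 2 * p$alpha_a
  p2$alpha_h <- 2 * p$alpha_h
  nc2 <- nullclines(p2, h_grid, a_grid)
  expect_equal(nc2$a_of_h$a, 2 * nc$a_of_h$a)
  expect_equal(nc2$h_of_a$h, 2 * nc$h_of_a$h)
  expect_error(nullclines(p, numeric(0), a_grid), "empty")

  # fixed point zeroes the nullcline equations ...
  fp <- fixed_point(p)
  scale_a <- p$alpha_a / p$delta * p$k_TL_a * p$tau_m_a
  scale_h <- p$alpha_h / p$delta * p$k_TL_h * p$tau_m_h
  expect_equal(fp[["a"]], scale_a * hill_repression(fp[["h"]], p$K_h, p$n_h),
               tolerance = 1e-8)
  expect_equal(fp[["h"]], scale_h * hill_activation(fp[["a"]], p$K_a, p$n_a),
               tolerance = 1e-8)
  # ... and the full derivatives are small relative to the production scale
  d <- ode_rhs(fp, p)
  expect_lt(max(abs(d[c("r_a", "a", "r_h", "h")])) / p$alpha_a, 0.05)

  # vanishing activator production sends the equilibrium towards the origin
  plow <- preset_free_oscillator(alpha = 3, R = 0.02)
  plow$alpha_a <- plow$alpha_a * 1e-6
  fplow <- fixed_point(plow)
  expect_lt(fplow[["a"]], 1e-2)
  expect_lt(fplow[["h"]], 1e-2)
})

test_that("equilibrated damped trajectory lands on the nullcline intersection", {
  p <- preset_free_oscillator(alpha = 0.3, R = 0.02)  # strongly damped regime
  fp <- fixed_point(p)
  tr <- continuous_limit_reference(p, horizon_h = 400, dt_h = 1)
  end <- tr[nrow(tr), ]
  expect_equal(end$a, fp[["a"]], tolerance = 0.05)
  expect_equal(end$h, fp[["h"]], tolerance = 0.05)
})

test_that("parameter containers validate, convert units, and round-trip configs", {
  expect_error(preset_free_oscillator(alpha = -1), "positive")
  expect_error(uniform_oscillator_params(alpha = 1, K_a = 20, K_h = 0, n = 3,
                                         k_TL = 0.02, tau_m = 12, delta = 1e-4),
               "positive")
  p <- uniform_oscillator_params(alpha = 5, K_a = 20, K_h = 2, n = 4,
                                 k_TL = 0.02, tau_m = 12, delta = 3e-4)
  expect_equal(p$alpha_a, p$alpha_h)
  expect_equal(p$alpha_a, 5e-3)      # pM/s -> nM/s
  expect_equal(p$tau_m_a, 720)       # min -> s
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_params(p, path)
    p2 <- read_params(path)
    expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
  }
  expect_error(write_params(p, "params.txt"), "extension")
})
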