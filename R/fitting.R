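# Levenberg-Marquardt least squares on a residual function.
#
# minpack.lm's formula interface (nlsLM) builds a stats::nlsModel at the
# solution, which fails on perfect (zero-residual) fits; calling nls.lm
# directly avoids that and perfect fits are routine here (noiseless
# synthetic data). Covariance is the usual first-order approximation
# sigma^2 (J'J)^{-1} from the converged Levenberg-Marquardt Hessian.
fit_least_squares <- function(resid_fn, start, lower = NULL, upper = NULL,
                              maxiter = 500) {
  out <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxiter))
  n <- length(resid_fn(out$par))
  p <- length(out$par)
  converged <- out$info %in% 1:3
  dof <- n - p
  # nls.lm's returned Hessian uses relative finite-difference steps that
  # collapse for parameters converging to exactly zero; rebuild J'J with
  # central differences and a floored step instead
  J <- vapply(seq_len(p), function(j) {
    h <- 1e-6 * max(abs(out$par[j]), 1e-3)
    pp <- out$par; pp[j] <- pp[j] + h
    pm <- out$par; pm[j] <- pm[j] - h
    (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }, numeric(n))
  vc <- tryCatch({
    sigma2 <- out$deviance / max(dof, 1)
    sigma2 * solve(crossprod(J))
  }, error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, p) else sqrt(pmax(diag(vc), 0))
  names(se) <- names(out$par)
  list(par = out$par, se = se, deviance = out$deviance, df = dof,
       converged = converged, info = out$info, message = out$message)
}
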