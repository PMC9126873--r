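#' Fit a Hill transfer curve to titration data
#'
#' Least-squares fit of a Hill model to a bulk titration of a regulator
#' protein against the normalized response of its target promoter:
#' `response = base + amp / (1 + (conc/K)^n)` for a repressor titration, or
#' `response = base + amp / (1 + (K/conc)^n)` for an activator titration.
#' Scale (`amp`) and offset (`base`) are free, so the response need not be
#' perfectly normalized. Confidence intervals at the 68% level are derived
#' from the fit covariance (t quantiles on the coefficient standard errors).
#'
#' The fit requires at least four distinct concentrations and a titration
#' range that actually spans the transition; data sitting entirely on one
#' plateau leave `K` and `n` unidentifiable and raise an estimation error.
#'
#' @param conc regulator concentrations (nM).
#' @param response measured normalized response at each concentration.
#' @param mode `"repression"` or `"activation"`.
#' @return An object of class `hill_fit`: list with `K`, `n`, `K_ci`,
#'   `n_ci` (68% intervals), `base`, `amp`, `mode` and the underlying `fit`.
#' @export
#' @examples
#' conc <- c(0.2, 0.5, 1, 2, 5, 10, 20)
#' resp <- 1 / (1 + (conc / 2.2)^2.1)
#' fit_hill(conc, resp, mode = "repression")
fit_hill <- function(conc, response, mode = c("repression", "activation")) {
  mode <- match.arg(mode)
  if (length(conc) != length(response)) stop("fit_hill: length mismatch", call. = FALSE)
  ok <- is.finite(conc) & is.finite(response) & conc > 0
  conc <- conc[ok]; response <- response[ok]
  if (length(unique(conc)) < 4) {
    stop("fit_hill: need at least 4 distinct positive concentrations", call. = FALSE)
  }
  df <- data.frame(conc = conc, y = response)
  span <- diff(range(response))
  if (span <= 0) stop("fit_hill: flat response, parameters unidentifiable", call. = FALSE)

  # midpoint of the response as K seed
  mid <- (max(response) + min(response)) / 2
  K0 <- conc[which.min(abs(response - mid))]
  model <- if (mode == "repression") {
    function(p) p[["base"]] + p[["amp"]] / (1 + (conc / p[["K"]])^p[["n"]])
  } else {
    function(p) p[["base"]] + p[["amp"]] / (1 + (p[["K"]] / conc)^p[["n"]])
  }
  fit <- fit_least_squares(
    function(p) response - model(p),
    start = c(K = K0, n = 2, base = min(response), amp = span),
    lower = c(K = 1e-9, n = 0.05, base = -Inf, amp = 1e-12),
    upper = c(K = Inf, n = 50, base = Inf, amp = Inf))
  if (!fit$converged) {
    stop("fit_hill: fit did not converge: ", fit$message, call. = FALSE)
  }
  if (any(!is.finite(fit$se[c("K", "n")]))) {
    stop("fit_hill: singular fit covariance, parameters unidentifiable", call. = FALSE)
  }
  co <- fit$par
  # transition must be covered by the titration, otherwise K is extrapolated
  if (co[["K"]] > 2 * max(conc) || co[["K"]] < min(conc) / 2) {
    stop("fit_hill: fitted threshold outside the titrated range; ",
         "titration does not span the transition", call. = FALSE)
  }
  q <- stats::qt(0.5 + 0.68 / 2, df = max(fit$df, 1))
  out <- list(K = co[["K"]], n = co[["n"]],
              K_ci = co[["K"]] + c(-1, 1) * q * fit$se[["K"]],
              n_ci = co[["n"]] + c(-1, 1) * q * fit$se[["n"]],
              base = co[["base"]], amp = co[["amp"]],
              mode = mode, fit = fit)
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s): K = %.3g nM [%.3g, %.3g], n = %.3g [%.3g, %.3g] (68%% CI)\n",
              x$mode, x$K, x$K_ci[1], x$K_ci[2], x$n, x$n_ci[1], x$n_ci[2]))
  invisible(x)
}
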