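#' Run one of the study's named analyses end to end
#'
#' Orchestrates the package's stages into the study's canonical numerical
#' experiments, writing tabular results (CSV), a JSON manifest sufficient to
#' re-run the bundle identically, and a rendered overview figure (PDF) to
#' `out_dir`. All downstream checks read the tables, never the figures.
#'
#' Available tags:
#' \describe{
#'   \item{`free_phase_diagram`}{free-oscillator phase metrics over a small
#'     (alpha, R) grid: regime classification, damping ratio, amplitude.}
#'   \item{`period_vs_delta`}{ACF periods of the free oscillator across
#'     refresh ratios, with the fitted proportionality constant of the
#'     `T = C*pi/delta` law.}
#'   \item{`sensitivity`}{period response to +30% parameter perturbations.}
#'   \item{`forced_entrainment`}{an entrained 1-cycle (`lambda = 1.48`):
#'     trace plus ACF period compared with the input period.}
#'   \item{`period_doubling`}{the 4-cycle at `lambda = 1.20`: trace, maxima,
#'     return map, rotation number.}
#'   \item{`bifurcation_1d`}{maxima heights over a `lambda` grid.}
#'   \item{`bifurcation_2d`}{rotation numbers over an (n, lambda) grid.}
#' }
#'
#' Default grid sizes are chosen to complete in minutes on one core while
#' resolving the qualitative structure; pass `...` overrides for denser
#' scans.
#'
#' @param tag one of the analysis tags above.
#' @param out_dir output directory; created if needed.
#' @param seed RNG seed recorded in the manifest (the bundles are
#'   deterministic unless synthetic noise is requested).
#' @param alpha_grid,R_grid grids for `free_phase_diagram` and
#'   `period_vs_delta`.
#' @param lambda_grid,n_grid grids for the bifurcation scans.
#' @param ... currently unused.
#' @return A list with the bundle's tables, invisibly; files are written to
#'   `out_dir`.
#' @export
run_study <- function(tag = c("free_phase_diagram", "period_vs_delta",
                              "sensitivity", "forced_entrainment",
                              "period_doubling", "bifurcation_1d",
                              "bifurcation_2d"),
                      out_dir = tempfile("cfclock_"), seed = 1L,
                      alpha_grid = c(0.3, 1, 3),
                      R_grid = c(0.1, 0.2, 0.3),
                      lambda_grid = seq(0.8, 1.6, by = 0.05),
                      n_grid = c(3, 4, 6, 8), ...) {
  tag <- match.arg(tag)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  res <- switch(tag,
    free_phase_diagram = wf_free_phase_diagram(out_dir, alpha_grid, R_grid),
    period_vs_delta = wf_period_vs_delta(out_dir, R_grid = seq(0.1, 0.4, length.out = 7)),
    sensitivity = wf_sensitivity(out_dir),
    forced_entrainment = wf_forced_point(out_dir, lambda = 1.48, tag = tag),
    period_doubling = wf_forced_point(out_dir, lambda = 1.20, tag = tag),
    bifurcation_1d = wf_bifurcation_1d(out_dir, lambda_grid),
    bifurcation_2d = wf_bifurcation_2d(out_dir, n_grid, lambda_grid)
  )
  manifest <- list(tag = tag, seed = seed,
                   created = format(Sys.time(), tz = "UTC"),
                   settings = res$settings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

wf_free_phase_diagram <- function(out_dir, alpha_grid, R_grid) {
  grid <- expand.grid(alpha = alpha_grid, R = R_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- preset_free_oscillator(alpha = grid$alpha[i], R = grid$R[i])
    tr <- run_reactor(p, reactor_protocol(R = grid$R[i], n_cycles = 192))
    pm <- phase_metrics(tr, channel = "rep_a")
    data.frame(alpha = grid$alpha[i], R = grid$R[i],
               delta = dilution_rate(grid$R[i]),
               regime = pm$regime, gamma = pm$gamma, A_inf = pm$A_inf,
               tau_eq_h = pm$tau_eq_h, n_maxima = pm$n_maxima)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out_dir, "phase_diagram.csv"), row.names = FALSE)
  fig <- ggplot2::ggplot(tab, ggplot2::aes(x = delta * 1e4, y = alpha,
                                           fill = regime)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dilution rate (1e-4/s)", y = "alpha (pM/s)",
                  title = "Free-oscillator phase diagram")
  ggplot2::ggsave(file.path(out_dir, "phase_diagram.pdf"), fig,
                  width = 5, height = 4)
  list(table = tab, settings = list(alpha_grid = alpha_grid, R_grid = R_grid,
                                    n_cycles = 192))
}

wf_period_vs_delta <- function(out_dir, R_grid) {
  # the scaling law concerns the limit-cycle period: simulate 120 h and
  # estimate on the equilibrated part (the startup transient would otherwise
  # inflate the ACF period at low dilution)
  rows <- lapply(R_grid, function(R) {
    p <- preset_free_oscillator(alpha = 3, R = R)
    tr <- run_reactor(p, reactor_protocol(R = R, n_cycles = 480))
    est <- acf_period(tr$rep_a[tr$time_h > 24], dt_h = tr$time_h[2] - tr$time_h[1])
    data.frame(R = R, delta = dilution_rate(R),
               T_acf_h = est$period_h, T_pred_h = predicted_period(dilution_rate(R)),
               uncertainty_h = est$uncertainty_h, n_maxima = est$n_maxima_used)
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$T_acf_h)
  x <- pi / tab$delta[ok] / 3600
  C <- sum(tab$T_acf_h[ok] * x) / sum(x^2)  # through-origin least squares
  utils::write.csv(tab, file.path(out_dir, "period_vs_delta.csv"), row.names = FALSE)
  jsonlite::write_json(list(C = C), file.path(out_dir, "period_fit.json"),
                       auto_unbox = TRUE, digits = NA)
  fig <- ggplot2::ggplot(tab, ggplot2::aes(x = delta * 1e4, y = T_acf_h)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = C * pi / delta / 3600), linetype = 2) +
    ggplot2::labs(x = "dilution rate (1e-4/s)", y = "ACF period (h)",
                  title = sprintf("T = C*pi/delta, C = %.3f", C))
  ggplot2::ggsave(file.path(out_dir, "period_vs_delta.pdf"), fig,
                  width = 5, height = 4)
  list(table = tab, C = C, settings = list(R_grid = R_grid, n_cycles = 288,
                                           alpha = 3))
}

wf_sensitivity <- function(out_dir) {
  p <- preset_free_oscillator(alpha = 3, R = 0.25)
  proto <- reactor_protocol(R = 0.25, n_cycles = 288)
  tab <- sensitivity_analysis(p, proto)
  utils::write.csv(tab, file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
  fig <- ggplot2::ggplot(tab, ggplot2::aes(x = stats::reorder(parameter, abs(delta_T_h)),
                                           y = delta_T_h)) +
    ggplot2::geom_col() + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "period change (h) for +30%",
                  title = "Period sensitivity")
  ggplot2::ggsave(file.path(out_dir, "sensitivity.pdf"), fig, width = 5, height = 4)
  list(table = tab, settings = list(alpha = 3, R = 0.25, n_cycles = 288,
                                    rel_change = 0.3))
}

wf_forced_point <- function(out_dir, lambda, tag) {
  p <- preset_forced_oscillator()
  res <- classify_forced_point(p, lambda)
  write_trace(res$trace, file.path(out_dir, "trace.csv"))
  utils::write.csv(res$maxima, file.path(out_dir, "maxima.csv"), row.names = FALSE)
  rmap <- return_map(res$maxima$height)
  utils::write.csv(rmap, file.path(out_dir, "return_map.csv"), row.names = FALSE)
  m_val <- if (res$rotation$chaotic) NA_integer_ else res$rotation$m
  post <- res$trace[res$trace$cycle >= 500, ]
  est <- acf_period(post$h, dt_h = 0.25)
  jsonlite::write_json(
    list(lambda = lambda, rotation_number = m_val,
         chaotic = res$rotation$chaotic,
         acf_period_h = est$period_h, T_in_h = 4),
    file.path(out_dir, "classification.json"), auto_unbox = TRUE, digits = NA)
  fig <- ggplot2::ggplot(rmap, ggplot2::aes(y_i, y_next)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "maximum i (nM)", y = "maximum i+1 (nM)",
                  title = sprintf("Return map, lambda = %.2f", lambda))
  ggplot2::ggsave(file.path(out_dir, "return_map.pdf"), fig, width = 4, height = 4)
  list(trace = res$trace, maxima = res$maxima, rotation = res$rotation,
       return_map = rmap, settings = list(lambda = lambda))
}

wf_bifurcation_1d <- function(out_dir, lambda_grid) {
  p <- preset_forced_oscillator()
  scan <- bifurcation_1d(p, lambda_grid)
  utils::write.csv(as.data.frame(scan), file.path(out_dir, "bifurcation_1d.csv"),
                   row.names = FALSE)
  fig <- ggplot2::ggplot(as.data.frame(scan),
                         ggplot2::aes(lambda, height, colour = channel)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "lambda", y = "maxima heights (nM)",
                  title = "Bifurcation diagram")
  ggplot2::ggsave(file.path(out_dir, "bifurcation_1d.pdf"), fig,
                  width = 6, height = 4)
  list(scan = scan, settings = list(lambda_grid = lambda_grid))
}

wf_bifurcation_2d <- function(out_dir, n_grid, lambda_grid) {
  p <- preset_forced_oscillator()
  scan <- bifurcation_2d(p, n_grid, lambda_grid)
  utils::write.csv(as.data.frame(scan), file.path(out_dir, "bifurcation_2d.csv"),
                   row.names = FALSE)
  df <- as.data.frame(scan)
  df$label <- ifelse(df$chaotic, "chaotic", as.character(df$m))
  fig <- ggplot2::ggplot(df, ggplot2::aes(lambda, factor(n), fill = label)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "lambda", y = "Hill coefficient n",
                  title = "Rotation numbers")
  ggplot2::ggsave(file.path(out_dir, "bifurcation_2d.pdf"), fig,
                  width = 6, height = 4)
  list(scan = scan, settings = list(n_grid = n_grid, lambda_grid = lambda_grid))
}
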