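# Channel order is load-bearing: the reactor map and the ODE right-hand side
# index states positionally.
STATE_CHANNELS <- c("r_a", "a", "r_h", "h", "rep_a", "rep_h", "x_in", "ref")

#' Instantaneous state of the reactor contents
#'
#' A named numeric vector holding the concentrations of all tracked species at
#' one instant: the activator and repressor mRNAs (`r_a`, `r_h`, nM), the
#' activator (sigma factor) and repressor (TetR) proteins (`a`, `h`, nM), the
#' two fluorescent reporter proteins co-expressed from the same mRNAs
#' (`rep_a`, `rep_h`, nM), the exogenously supplied input species (`x_in`,
#' nM: added TetR, or inducer depending on the forcing mode), and a
#' non-reacting reference-dye channel (`ref`, arbitrary units) that is only
#' diluted.
#'
#' @param r_a,a,r_h,h,rep_a,rep_h,x_in,ref non-negative concentrations
#'   (nM; `ref` in arbitrary units). Default is the empty reactor (all zero).
#' @return A named numeric vector of class `circuit_state`.
#' @export
#' @examples
#' circuit_state()                 # empty reactor
#' circuit_state(x_in = 50)        # spiked input
circuit_state <- function(r_a = 0, a = 0, r_h = 0, h = 0,
                          rep_a = 0, rep_h = 0, x_in = 0, ref = 0) {
  s <- c(r_a = r_a, a = a, r_h = r_h, h = h,
         rep_a = rep_a, rep_h = rep_h, x_in = x_in, ref = ref)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("circuit_state: all concentrations must be finite and non-negative",
         call. = FALSE)
  }
  class(s) <- c("circuit_state", "numeric")
  s
}

as_circuit_state <- function(x) {
  stopifnot(is.numeric(x), length(x) == length(STATE_CHANNELS))
  s <- as.numeric(x)
  names(s) <- STATE_CHANNELS
  class(s) <- c("circuit_state", "numeric")
  s
}

#' @export
print.circuit_state <- function(x, ...) {
  cat("Circuit state (nM; ref in a.u.):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
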