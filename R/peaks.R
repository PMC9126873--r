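# Local maxima of a sampled signal.
#
# A candidate peak is a sample strictly above its left neighbour and at least
# as high as its right neighbour (plateaus yield their first sample). The
# optional prominence filter drops peaks whose height above the deeper of the
# two flanking valleys (minima down to the trace ends or the neighbouring
# peaks) is below `prominence_frac` of the signal's dynamic range; this
# suppresses noise-born wiggles on measured traces. prominence_frac = 0
# keeps every candidate (appropriate for noiseless simulations).
find_local_maxima <- function(x, prominence_frac = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  cand <- which(d[-(n - 1)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand) || prominence_frac <= 0) return(cand)
  rng <- diff(range(x))
  if (rng <= 0) return(integer(0))
  keep <- vapply(seq_along(cand), function(j) {
    i <- cand[j]
    left_from <- if (j == 1) 1L else cand[j - 1L]
    right_to <- if (j == length(cand)) n else cand[j + 1L]
    prom <- x[i] - max(min(x[left_from:i]), min(x[i:right_to]))
    prom >= prominence_frac * rng
  }, logical(1))
  cand[keep]
}

find_local_minima <- function(x, prominence_frac = 0) {
  find_local_maxima(-x, prominence_frac)
}
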