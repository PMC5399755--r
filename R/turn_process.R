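## Turn-event process: inhomogeneous Poisson arrivals, merged into
## episodes, with the arrival intensity calibrated so that the episode
## rate equals the requested turn_rate_fn.
##
## Merging arrivals closer than the effective dead time
##   d = turn_duration + 1/frame_rate
## (overlapping postures plus the one-frame camera resolution) thins the
## episode rate of a Poisson process from lambda' to lambda'*exp(-lambda'*d).
## We invert that relation pointwise -- solve x*exp(-x) = lambda*d on the
## principal branch (x < 1) -- so the merged episode starts occur at the
## requested rate lambda(t) and binned episode counts are unbiased.

## Solve x * exp(-x) = c for x in [0, 1), vectorized. Requires c < 1/e.
solve_rate_inflation <- function(cc) {
  stopifnot(all(cc >= 0), all(cc < exp(-1)))
  x <- cc # good start for small c
  for (i in 1:50) {
    f <- x * exp(-x) - cc
    fp <- (1 - x) * exp(-x)
    step <- f / fp
    x <- pmin(pmax(x - step, 0), 1 - 1e-9)
    if (max(abs(step)) < 1e-12) break
  }
  x
}

## Draw turn episodes on [0, duration_s]. rate_fn in turns/min.
## Returns a data.frame(start_s, end_s), sorted, non-overlapping.
## Uses the current RNG state (callers seed it).
sample_turn_intervals <- function(rate_fn, duration_s, turn_duration_s,
                                  frame_rate_hz) {
  d_eff <- turn_duration_s + 1 / frame_rate_hz
  lambda <- function(t) rate_fn(t) / 60 # turns/s
  grid <- seq(0, duration_s, length.out = 1024)
  lam_g <- lambda(grid)
  if (max(lam_g) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  inflate <- function(lam) {
    x <- solve_rate_inflation(lam * d_eff)
    ifelse(lam > 0, x / d_eff, 0)
  }
  lam_max <- max(inflate(lam_g)) * (1 + 1e-9)
  ## homogeneous arrivals at lam_max, thinned to the compensated intensity
  n <- rpois(1, lam_max * duration_s)
  if (n == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  cand <- sort(runif(n, 0, duration_s))
  keep <- runif(n) < inflate(lambda(cand)) / lam_max
  starts <- cand[keep]
  if (length(starts) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  ## merge arrivals within the effective dead time into one episode
  ep_start <- starts[1]
  ep_end <- starts[1] + turn_duration_s
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(starts) > 1) {
    for (s in starts[-1]) {
      if (s < ep_end + 1 / frame_rate_hz) {
        ep_end <- s + turn_duration_s
      } else {
        out_s <- c(out_s, ep_start); out_e <- c(out_e, ep_end)
        ep_start <- s; ep_end <- s + turn_duration_s
      }
    }
  }
  out_s <- c(out_s, ep_start); out_e <- c(out_e, ep_end)
  data.frame(start_s = out_s, end_s = pmin(out_e, duration_s))
}
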