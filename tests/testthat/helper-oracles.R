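# Independent brute-force oracles used across the suite.

# Literal five-inequality binning from a trace's own statistics, written
# independently of the pipeline.  Valid for right-skewed traces where the
# thresholds are strictly increasing (median < mean, SD > 0), which
# random log-normal traces give.
oracle_codes <- function(v) {
  med <- median(v)
  mu <- mean(v)
  s <- sd(v)
  stopifnot(med < mu, s > 0)
  vapply(v, function(x) {
    if (x < med) 0L
    else if (x < mu) 1L
    else if (x < mu + s) 2L
    else if (x < mu + 2 * s) 3L
    else 4L
  }, integer(1))
}

# numeric equilibrium root of (Bmax - B)(L - B)/B = Kd on [0, min(Bmax, L)]
oracle_bound <- function(dose, Kd, Bmax) {
  if (dose == 0) return(0)
  f <- function(B) (Bmax - B) * (dose - B) - Kd * B
  uniroot(f, c(0, min(Bmax, dose)), tol = 1e-14)$root
}

random_trace <- function(n = 60) {
  net <- tibble::tibble(position = seq_len(n),
                        net = stats::rlnorm(n, -1, 1))
  normalize_by_region_median(net, "rand")
}
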