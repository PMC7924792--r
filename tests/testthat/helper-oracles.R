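# Closed-form oracles, written independently of the package internals.

# logistic-with-death first-passage time from N0 down to N1 at constant
# growth rate r: dN/dt = r N (1 - N/K) - delta N
oracle_passage_time <- function(r, delta, K, N0, N1) {
  if (r == 0) return(log(N0 / N1) / delta)
  alpha <- r - delta
  if (alpha == 0) return((K / r) * (1 / N1 - 1 / N0))
  Kp <- K * alpha / r
  (1 / alpha) * log(N1 * (Kp - N0) / (N0 * (Kp - N1)))
}

# logistic-with-death trajectory N(t)
oracle_trajectory <- function(r, delta, K, N0, t) {
  alpha <- r - delta
  if (alpha == 0) return(N0 / (1 + (r / K) * N0 * t))
  Kp <- K * alpha / r
  Kp * N0 * exp(alpha * t) / (Kp + N0 * (exp(alpha * t) - 1))
}

# small Monte Carlo batch returning the rescue fraction
rescue_fraction <- function(p, n, seed0) {
  mean(vapply(seq_len(n), function(i)
    run_simulation(p, seed = seed0 + i,
                   record_stride = 0L)$verdict == "rescued", logical(1)))
}
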