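# evorescue

Hybrid deterministic–stochastic simulations and analytic theory for
**evolutionary rescue in populations engaged in positive interactions**.

When an environment abruptly deteriorates — a death rate δ exceeding the
ancestral growth rate r_A — a population declines toward extinction and
survives only if faster-growing mutants (r_M > δ) arise and spread in
time. evorescue quantifies how that race is altered by positive
interactions, for researchers in eco-evolutionary dynamics, microbial
ecology, and conservation who want reproducible rescue-probability
estimates and the matching closed-form approximations:

* **cooperation** — a strong Allee effect: growth rates drop by a factor
  (1 − ρ) when the population is below a critical size N_c, so mutants
  must establish *before* the total crosses N_c;
* **obligate mutualism** — two species each require the *partner's*
  density above N_c and compete for shared resources, so rescue needs two
  independent mutation events and adaptation of one species accelerates
  the decline of the other;
* **cooperator–cheater dynamics** — cheaters enjoy the cooperators'
  public goods (advantage b above N_c) without paying for them, park the
  cooperator population near N_c, and all but abolish rescue.

All compartments follow logistic growth with death,
dN/dt = r(·) N (1 − N_T/K) − δN, where the growth rate r(·) switches
between r and r(1 − ρ) at the critical size (a smooth Hill-type response
is available too). The only stochastic element is the Poisson arrival of
mutants, with mean μ·A·Δt per interval — the hybrid scheme these models
were built around. The per-interval integrate/inject/clamp cycle runs in
compiled code; 1000 replicates of a default scenario take well under a
second.

The analytic side computes the **rescue time window** — the interval of
mutant-arrival times from which a single mutant can still establish and
reach N_c — by root-finding on the deterministic flow, and the rescue
probability as the chance that at least one mutant arises inside it,
P = 1 − exp(−μ ∫ A(t) dt).

## Worked example

```r
library(evorescue)

p <- rescue_params("cooperation")  # K = 1000, N_c = 30, rho = 0.5,
                                   # r_A = 1, r_M = 2, delta = 1.1, mu = 3e-4
rescue_window(p)
#> <rescue_window> decline 13.71, mutant growth 0.5757, window 13.13

rescue_probability_theory(p)
#> [1] 0.3473945

estimate_rescue_probability(p, n_replicates = 1000, master_seed = 10001)
#>   p_hat    ci_low  ci_high
#> 1 0.343 0.3142286 0.372973
```

The ancestor takes 13.71 time units to decline from K to the critical
size; a mutant lineage needs about 0.58 units to establish, leaving a
13.13-unit window during which an arriving mutant can still save the
population. The closed-form arrival probability over that window (0.347)
matches the Monte Carlo estimate from 1000 replicate simulations (0.343,
95% Wilson interval [0.314, 0.373]).

Sweeps, family comparisons and growth-rate matching follow the same
pattern:

```r
rescue_sweep(data.frame(N_c = c(10, 60, 150)), p, n_replicates = 500,
             master_seed = 1)
compare_model_families(data.frame(N_c = 30), p, n_replicates = 500,
                       master_seed = 1)
matched_growth_ratio(p, c("cooperation", "baseline"), n_replicates = 200,
                     master_seed = 1)
```

A command-line interface wraps the same operations for config-driven
runs (`simulate`, `sweep`, `theory`, `compare`, `match-ratio`), reading
YAML/JSON configs and writing CSV/JSON outputs plus a resolved-config
sidecar from which any run can be reproduced exactly:

```sh
Rscript inst/cli/evorescue simulate --config run.yaml --out_dir out/
```

See `vignettes/rescue-models.Rmd` for the full model definitions, the
rescue-window theory, and every numerical choice.

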