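---
title: "Models and methods: evolutionary rescue under positive interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: evolutionary rescue under positive interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

evorescue simulates *evolutionary rescue*: a population whose environment
has abruptly deteriorated declines toward extinction, and survives only if
faster-growing mutants arise and spread in time. The package asks how that
race is changed when individuals depend on each other — through
intraspecies cooperation, obligate mutualism between two species, or
cooperation undermined by cheaters.

## The models

All variants share a logistic backbone with an environmental death rate.
Each compartment (species × genotype) with abundance $N$ follows

$$\frac{dN}{dt} = r(\cdot)\, N \left(1 - \frac{N_T}{K}\right) - \delta N,$$

where $K$ is the carrying capacity, $\delta$ the death rate imposed by the
stress, $N_T$ the crowding total, and $r(\cdot)$ a growth rate that depends
on a *reference density* through a strong Allee effect: the full rate $r$
applies when the reference exceeds the critical population size $N_c$, and
the reduced rate $r(1-\rho)$ applies at or below it, with Allee depth
$\rho \in [0,1]$.

The variants differ only in what the reference and the crowding total are:

| variant | growth-rate reference | crowding total |
|---|---|---|
| `baseline` | — (no Allee effect) | own species total |
| `cooperation` | own species total $A+M$ | own species total |
| `mutualism` | *partner's* total | grand total (shared resources) |
| `mutualism_no_competition` | partner's total | own species total |
| `cheater` | cooperator total $N_\mathrm{coop}$ | grand total |

In the cheater variant, cooperators follow the usual response while
cheaters grow at $r(1+b)$ when cooperators are abundant (they enjoy the
public goods without paying for them) and at $r(1-\rho)(1-a)$ below $N_c$
(cooperators have preferential access to their own goods, with advantage
$a$). Ancestors ($A$, rate $r_A$) and mutants ($M$, rate $r_M > r_A$)
differ only in their exponential growth rate.

A `smooth` Allee form is also available: a Hill-type sigmoid
$r\left(1 - \rho\, N_c^h/(N_c^h + N_\mathrm{ref}^h)\right)$, continuous,
equal to the step form in the limits $N_\mathrm{ref} \to 0,\infty$ and to
$r(1-\rho/2)$ at the threshold, converging to the step form as
$h \to \infty$. The exact functional form is this package's choice; its
role is only to show that results do not hinge on the discontinuity, and
the step form (which permits the analytic treatment below) is the default.

## The hybrid simulation scheme

Only mutation is stochastic. Each replicate advances in reporting
intervals of length $\Delta t = 0.01$:

1. the deterministic dynamics are advanced by $\Delta t$ with an adaptive
   embedded Cash–Karp Runge–Kutta (4/5) integrator (relative tolerance
   $10^{-8}$); non-finite states raise an error rather than propagating;
2. for each species, a Poisson number of new mutants with mean
   $\mu A \Delta t$ is injected into the mutant compartment, with $A$ the
   ancestor abundance at the interval start (ancestors are not
   decremented; at the mutation rates of interest, $\mu \le 10^{-2}$, the
   non-conservation bias is far below one individual per replicate);
3. any compartment below the extinction threshold (1 individual) is set
   to zero.

A run ends *rescued* when the mutant compartment reaches
$\max(N_c, 1)$ — for mutualism, in both species; for the cheater model,
when the cooperator mutant holds that size once the cheater compartments
are extinct (or still holds it at the time horizon: adapted cheaters can
crash an already-risen cooperator mutant, so the verdict cannot be issued
earlier). It ends *extinct* when every compartment is zero. The horizon
defaults to ten times the deterministic ancestor-extinction time, so
undecided runs are essentially confined to no-stress parameterizations;
undecided runs count as non-rescues.

Runs start at stress onset with the ancestor at its deterministic
pre-stress equilibrium ($K$ for one species; total $K$ for competing
mutualists, split by `initial_fraction`; $K$ per species without
competition). Pre-stress growth is deterministic and identical across
replicates, so simulating it would only burn CPU. The cheater variant is
the exception: it needs a burn-in on the cooperator–cheater oscillation.

### The cheater burn-in needs pre-stress mortality

With the equations above and no mortality, every compartment is
non-decreasing before the stress, so the documented pre-stress
*oscillation* of cooperators around $N_c$ — cheaters outcompeting
cooperators above the threshold, cooperators recovering below it — cannot
exist. The burn-in therefore runs with a baseline death rate
`burn_in_delta` (default 0.3; think dilution or background mortality).
With the default $a = 0.9$, $b = 0.3$ this produces a sustained
oscillation of the cooperator total around $N_c$ (crossing it many times
per 100 time units) with cheaters coexisting at high density. The burn-in
is deterministic, so all replicates experience stress from the same state;
its endpoint is cached across replicates.

## The rescue time window

The analytic approximation rests on first-passage times of the
deterministic flow, computed by dense-output integration with root finding
(`deSolve::lsodar`), restarting the solver at every crossing of $N_c$ so
each segment has a smooth right-hand side. Closed-form
exponential/logistic formulas are used only as test oracles (agreement to
$10^{-6}$ relative error).

`rescue_window()` reports the classical decomposition — the time
`t_decline` for the ancestor to fall to $N_c$, minus the time `t_grow` a
mutant lineage needs to grow to $N_c$ — but both edges are computed
operationally, as properties of the flow the simulator actually runs: a
single mutant (one extinction-threshold unit) is seeded at a candidate
arrival time on the declining background, and *establishes* if it reaches
$N_c$ before dipping back below the threshold (the dip emulates the
simulator's extinction clamp). Bisection over the seeding time yields the
interval of viable arrivals. Two effects distinguish this from the bare
picture:

* **Early arrivals die.** Near stress onset the population is close to
  $K$, the logistic factor is near zero, and a fresh mutant's net growth
  rate $r_M(1 - N_T/K) - \delta$ is negative; the clamp removes it within
  an interval. The viable window therefore *starts* only once the total
  has declined below $K(1 - \delta/r_M)$.
* **Late arrivals get farther than the bare estimate suggests.** The
  mutant's own abundance counts toward the growth-rate reference, so the
  total can stay above $N_c$ well after the ancestor alone has crossed it.

`mutant_growth_time(method = "bare")` keeps the textbook approximation
$\log(N_c)/(r_M - \delta)$ for reference.

`rescue_probability_theory()` is then the probability that at least one
mutant arises inside the viable window under the Poisson arrival model:

$$P = 1 - \exp\!\left(-\mu \int_{\tau_\mathrm{lo}}^{\tau_\mathrm{hi}} A(t)\, dt\right),$$

with $A(t)$ the deterministic ancestor trajectory. For the baseline
variant the window runs to the ancestor's extinction time. For mutualism
without competition the species adapt independently and $P$ is the product
of two single-species probabilities — the square, when symmetric. For
mutualism with competition, $P$ multiplies the first species' arrival
probability by the second species' arrival probability over a *truncated*
window: the background is recomputed with the first species' mutant seeded
at its conditional median arrival time and held on its adapted course, so
the partner's ancestors decline faster under the added competition, and
the second window ends at the latest arrival whose mutant still reaches
$N_c$ before its species total collapses below it. This one-level
conditioning is an approximation; its contract is the agreement property
below, not the formula itself.

The approximation treats arrivals as independent single-lineage events. At
extreme mutation rates (around $\mu \gtrsim 3\times10^{-3}$ for the
default conditions) mutants arrive every few intervals and *accumulate*,
and populations can be rescued even where the single-mutant window is
zero; the zero-window prediction is a statement about the sparse-arrival
regime.

## Study conditions and what the tests show

The default parameter set — $K = 1000$, $r_A = 1$, $r_M = 2$,
$\rho = 0.5$, $\delta = 1.1$, $N_c = 30$, $\mu = 3\times10^{-4}$,
$\Delta t = 0.01$, extinction below 1 — was chosen once so that every
interaction type sits in the rescue-relevant regime
($r_A < \delta$ and $r_M > \delta > r_M(1-\rho)$) with mid-range rescue
probabilities: gentle stress ($\delta - r_A = 0.1$) keeps decline times
long enough that even the mutualism variants, whose per-species
populations start at $K/2$ and are crowded by the grand total, retain a
positive window. Probabilities are estimated from independent replicates
(1000 by default; tests use 200–500 where a
wider tolerance is stated) with 95% Wilson score intervals, and
per-replicate seeds derived from a master seed by replicate index, so
every sweep is exactly reproducible and rows are independent of
evaluation order.

The cheater-model demonstrations use two configurations. The defaults
($a = 0.9$, $b = 0.3$) show the typical fate: the oscillation parks
cooperators near $N_c$, the window vanishes, and rescue is never observed.
`cheater_extreme_params()` freezes the regime in which rescue is
observable at all: a three-orders-of-magnitude cooperator advantage at low
density ($a = 0.999$), with the burn-in length (96) chosen so stress lands
in the oscillation phase where cheaters are near their minimum — outside
that phase band (about 5 time units of a ~40-unit period) even an
immediately-arising mutant cannot establish. In that regime rescue is
*non-monotone* in the mutation rate: beyond $\mu = 10^{-3}$ adapted
cheaters also arise, outcompete the rising cooperator mutant, and both
collapse. Every rescued run ends with the cheater compartments extinct.

What passing tests do and do not show: the simulator reproduces its own
deterministic oracles to integrator precision, and the analytic theory
tracks Monte Carlo estimates within 0.1 across the rescue-relevant grids
exercised. None of this validates the models against real populations —
there is no demographic (birth–death) noise beyond mutant arrivals, no
spatial structure, no environmental fluctuation, and the step Allee
response is a deliberate idealization.

## Numerical choices

* Step-response boundary: exact equality $N_\mathrm{ref} = N_c$ takes the
  *reduced* branch (strict `>` keeps the high branch) — a measure-zero
  choice made once, matching the branch condition as written.
* Integrator: Cash–Karp 4(5) with rtol $10^{-8}$, atol $10^{-10}$ per
  interval in the engine; `lsodar` with rtol $10^{-10}$ in the theory
  module; tiny negative abundances from the solve are clamped to zero.
* Extinction clamping happens at interval boundaries only, never inside
  the ODE solve, so adaptive stepping is undisturbed.
* The window-edge bisections resolve arrival times to $10^{-3}$ of the
  decline time; probability integrals interpolate a 400-point dense
  solve.
* Replicate seed spawning: `(master_seed + i - 1) mod (2^31 - 1)`; grid
  row $r$ of a sweep starts at `master_seed + (r-1) * n_replicates`.

## Worked example

```r
library(evorescue)

p <- rescue_params("cooperation")   # defaults described above
rescue_window(p)
#> <rescue_window> decline 13.71, mutant growth 0.5757, window 13.13

rescue_probability_theory(p)
#> [1] 0.3473945

estimate_rescue_probability(p, n_replicates = 1000, master_seed = 10001)
#> p_hat 0.343, 95% CI [0.3142, 0.3730]
```

The CLI mirrors the same operations from YAML/JSON configs:

```sh
Rscript inst/cli/evorescue sweep --config sweep.yaml --out_dir runs/
```
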