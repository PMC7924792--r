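#' Model parameters for an evolutionary-rescue simulation
#'
#' Builds a validated parameter set for one model variant. All rates are per
#' unit time; abundances are in individuals. Two-species variants
#' (`mutualism`, `mutualism_no_competition`, `cheater`) accept length-2
#' vectors for `r_A`, `r_M` and `mu` (recycled from length 1); in the cheater
#' variant species 1 is the cooperator and species 2 the cheater.
#'
#' The stress scenario starts at `t = 0` with the death rate `delta` already
#' at its stressed value and the population at its pre-stress equilibrium
#' (pre-stress growth is deterministic and identical across replicates, so it
#' is not simulated). The cheater variant is the exception: it runs a
#' deterministic burn-in of length `burn_in` with death rate `burn_in_delta`
#' before stress onset, so that stress hits the oscillating cooperator-cheater
#' quasi-attractor.
#'
#' @param model_variant one of `"baseline"`, `"cooperation"`, `"mutualism"`,
#'   `"mutualism_no_competition"`, `"cheater"`.
#' @param r_A ancestral exponential growth rate (length 1 or 2).
#' @param r_M mutant exponential growth rate (length 1 or 2); rescue requires
#'   `r_M > delta`.
#' @param K carrying capacity shared by all compartments.
#' @param N_c critical population size: below it growth rates are reduced by
#'   the factor `1 - rho` (strong Allee effect).
#' @param rho Allee depth in `[0, 1]`; `rho = 0` removes the Allee effect.
#' @param delta environmental death rate after stress onset.
#' @param mu mutation rate per individual per unit time (length 1 or 2 for
#'   two-species variants).
#' @param a cooperator low-density advantage (cheater variant only): below
#'   `N_c` cheaters grow at `r (1 - rho) (1 - a)`.
#' @param b cheater high-density advantage: above `N_c` cheaters grow at
#'   `r (1 + b)`.
#' @param allee_form `"step"` (piecewise-constant response, the default) or
#'   `"smooth"` (Hill-type sigmoid response).
#' @param smooth_steepness Hill coefficient `h > 0` of the smooth response.
#' @param dt integration/reporting interval; mutants are injected once per
#'   interval.
#' @param extinction_threshold abundance below which a compartment is set to
#'   zero (extinct).
#' @param t_max maximum simulated time before a verdict is declared by
#'   final-state inspection; default 10x the deterministic ancestor
#'   extinction time.
#' @param initial_fraction fraction of total initial density assigned to
#'   species 1 in the two-species mutualism variants.
#' @param burn_in length of the deterministic pre-stress burn-in (cheater
#'   variant only).
#' @param burn_in_delta death rate during the burn-in. A positive value is
#'   required for the cooperator-cheater oscillation around `N_c` to exist;
#'   with no mortality every compartment is non-decreasing pre-stress.
#' @param burn_in_start named vector `c(coop = ..., cheat = ...)` of burn-in
#'   starting abundances; defaults to `c(N_c, N_c / 10)`.
#'
#' @return an object of class `rescue_params` (a validated named list).
#' @examples
#' p <- rescue_params("cooperation", N_c = 50, mu = 3e-4)
#' p
#' classify_regime(p)
#' @export
rescue_params <- function(model_variant = "cooperation",
                          r_A = 1, r_M = 2, K = 1000, N_c = 30, rho = 0.5,
                          delta = 1.1, mu = 3e-4, a = 0.9, b = 0.3,
                          allee_form = c("step", "smooth"),
                          smooth_steepness = 4,
                          dt = 0.01, extinction_threshold = 1,
                          t_max = NULL, initial_fraction = 0.5,
                          burn_in = 100, burn_in_delta = 0.3,
                          burn_in_start = NULL) {
  model_variant <- match.arg(model_variant, .variant_levels)
  allee_form <- match.arg(allee_form)
  two <- model_variant %in% c("mutualism", "mutualism_no_competition",
                              "cheater")
  r_A <- rep_len(as.numeric(r_A), if (two) 2L else 1L)
  r_M <- rep_len(as.numeric(r_M), if (two) 2L else 1L)
  mu  <- rep_len(as.numeric(mu),  if (two) 2L else 1L)
  if (is.null(burn_in_start)) burn_in_start <- c(coop = N_c, cheat = N_c / 10)

  p <- structure(list(
    model_variant = model_variant,
    r_A = r_A, r_M = r_M, K = K, N_c = N_c, rho = rho, delta = delta,
    mu = mu, a = a, b = b,
    allee_form = allee_form, smooth_steepness = smooth_steepness,
    dt = dt, extinction_threshold = extinction_threshold,
    t_max = t_max, initial_fraction = initial_fraction,
    burn_in = burn_in, burn_in_delta = burn_in_delta,
    burn_in_start = burn_in_start),
    class = "rescue_params")
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants (`rho` in `[0,1]`, all rates
#' non-negative, `K > 0`, `dt > 0`, ...) and stops with an informative
#' message on the first violation.
#'
#' @param p a [rescue_params()] object.
#' @return `p`, invisibly.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "rescue_params"))
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  chk(p$model_variant %in% .variant_levels, "unknown model_variant")
  chk(all(p$r_A >= 0) && all(p$r_M >= 0), "growth rates must be >= 0")
  chk(all(p$mu >= 0), "mutation rates must be >= 0")
  chk(p$delta >= 0, "death rate delta must be >= 0")
  chk(p$rho >= 0 && p$rho <= 1, "rho must lie in [0, 1]")
  chk(p$K > 0, "carrying capacity K must be > 0")
  chk(p$N_c >= 0, "critical population size N_c must be >= 0")
  chk(p$dt > 0, "time step dt must be > 0")
  chk(p$extinction_threshold >= 0, "extinction_threshold must be >= 0")
  chk(p$smooth_steepness > 0, "smooth_steepness must be > 0")
  chk(p$initial_fraction > 0 && p$initial_fraction < 1,
      "initial_fraction must lie in (0, 1)")
  chk(is.null(p$t_max) || p$t_max > 0, "t_max must be > 0")
  if (p$model_variant == "cheater") {
    chk(p$a >= 0 && p$a <= 1, "cooperator advantage a must lie in [0, 1]")
    chk(p$b >= 0, "cheater advantage b must be >= 0")
    chk(p$burn_in >= 0 && p$burn_in_delta >= 0,
        "burn-in settings must be >= 0")
    chk(all(p$burn_in_start >= 0), "burn_in_start abundances must be >= 0")
  }
  invisible(p)
}

#' Classify the dynamical regime of a parameter set
#'
#' Rescue is a nontrivial question only when the ancestor declines under
#' stress (`r_A < delta`) while the mutant can grow above the critical size
#' but not below it (`r_M > delta > r_M (1 - rho)`).
#'
#' @param p a [rescue_params()] object.
#' @return one of `"trivially_safe"` (no decline), `"deterministic_extinction"`
#'   (mutants cannot grow either), or `"rescue_relevant"`.
#' @export
classify_regime <- function(p) {
  validate_params(p)
  if (p$delta <= max(p$r_A)) return("trivially_safe")
  if (min(p$r_M) <= p$delta) return("deterministic_extinction")
  "rescue_relevant"
}

#' @export
print.rescue_params <- function(x, ...) {
  cat("<rescue_params>", x$model_variant,
      if (x$allee_form == "smooth")
        sprintf("(smooth Allee, h = %g)", x$smooth_steepness)
      else "(step Allee)", "\n")
  fmt <- function(v) paste(signif(v, 6), collapse = ", ")
  cat(sprintf("  r_A = %s  r_M = %s  K = %g  N_c = %g  rho = %g\n",
              fmt(x$r_A), fmt(x$r_M), x$K, x$N_c, x$rho))
  cat(sprintf("  delta = %g  mu = %s  dt = %g  extinction < %g\n",
              x$delta, fmt(x$mu), x$dt, x$extinction_threshold))
  if (x$model_variant == "cheater")
    cat(sprintf("  a = %g  b = %g  burn_in = %g @ delta = %g\n",
                x$a, x$b, x$burn_in, x$burn_in_delta))
  cat(sprintf("  regime: %s\n", classify_regime(x)))
  invisible(x)
}

# fields serialized to/from flat config mappings
.param_keys <- c("model_variant", "r_A", "r_M", "K", "N_c", "rho", "delta",
                 "mu", "a", "b", "allee_form", "smooth_steepness", "dt",
                 "extinction_threshold", "t_max", "initial_fraction",
                 "burn_in", "burn_in_delta", "burn_in_start")

#' Serialize parameters to a flat list
#'
#' The result round-trips through JSON or YAML and back via
#' [params_from_list()].
#'
#' @param p a [rescue_params()] object.
#' @return a named list of plain vectors.
#' @export
params_to_list <- function(p) {
  validate_params(p)
  out <- unclass(p)[.param_keys]
  out$burn_in_start <- as.numeric(out$burn_in_start)
  out[!vapply(out, is.null, logical(1))]
}

#' Rebuild parameters from a flat list
#'
#' Inverse of [params_to_list()]; unknown keys are rejected so that config
#' typos fail loudly.
#'
#' @param x a named list, e.g. parsed from YAML or JSON.
#' @return a [rescue_params()] object.
#' @export
params_from_list <- function(x) {
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), .param_keys)
  if (length(unknown) > 0)
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(x$burn_in_start))
    x$burn_in_start <- stats::setNames(as.numeric(x$burn_in_start),
                                       c("coop", "cheat"))
  do.call(rescue_params, x)
}

# integer code used by the compiled engine
variant_code <- function(variant) {
  match(variant, .variant_levels) - 1L
}

# packs a rescue_params into the flat numeric vector the engine expects
pack_params <- function(p) {
  r_A <- rep_len(p$r_A, 2L); r_M <- rep_len(p$r_M, 2L)
  mu <- rep_len(p$mu, 2L)
  c(variant_code(p$model_variant),
    r_A[1], r_A[2], r_M[1], r_M[2],
    p$K, p$N_c, p$rho, p$delta,
    mu[1], mu[2], p$a, p$b,
    as.integer(p$allee_form == "smooth"), p$smooth_steepness,
    p$dt, p$extinction_threshold)
}

#' Cheater-model parameters in the extreme cooperator-advantage regime
#'
#' Rescue of cooperative populations invaded by cheaters is only observed
#' when cooperators hold an orders-of-magnitude growth advantage over
#' cheaters at low density. This helper returns such a configuration:
#' `a = 0.999` (a 1000-fold low-density advantage), a moderate cheater
#' benefit `b = 0.3`, and a burn-in length placing stress onset in the
#' oscillation phase where cheaters are near their minimum -- the only
#' phase in which a cooperator mutant can establish at all. Note that
#' raising the mutation rate beyond `1e-3` *lowers* the rescue probability
#' here, because adapted cheaters then arise too and crash the rising
#' cooperator mutant.
#'
#' @param ... overrides passed on to [rescue_params()].
#' @return a [rescue_params()] object.
#' @export
cheater_extreme_params <- function(...) {
  defaults <- list(model_variant = "cheater", N_c = 30, r_M = 2.15,
                   mu = 1e-3, a = 0.999, b = 0.3, burn_in = 96,
                   burn_in_delta = 0.4)
  do.call(rescue_params, modifyList(defaults, list(...)))
}

#' Species labels of a model variant
#' @param p a [rescue_params()] object.
#' @return character vector of species labels (length 1 or 2).
#' @export
species_labels <- function(p) {
  switch(p$model_variant,
         baseline = , cooperation = "sp1",
         mutualism = , mutualism_no_competition = c("sp1", "sp2"),
         cheater = c("coop", "cheat"))
}
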