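#' Population state
#'
#' A population state holds the abundance of every (species, genotype)
#' compartment at one simulation time. Internally all variants share one
#' fixed layout `c(A1, M1, A2, M2)` (species-1 ancestor, species-1 mutant,
#' species-2 ancestor, species-2 mutant); single-species variants leave
#' species 2 at zero, and the cheater variant maps species 1 to cooperators
#' and species 2 to cheaters.
#'
#' @param A1,M1,A2,M2 non-negative compartment abundances.
#' @param t simulation time attached to the state.
#' @return an object of class `population_state`.
#' @examples
#' population_state(A1 = 1000)
#' @export
population_state <- function(A1 = 0, M1 = 0, A2 = 0, M2 = 0, t = 0) {
  y <- c(A1 = as.numeric(A1)[1], M1 = as.numeric(M1)[1],
         A2 = as.numeric(A2)[1], M2 = as.numeric(M2)[1])
  if (any(y < 0)) stop("abundances must be >= 0", call. = FALSE)
  structure(y, t = t, class = "population_state")
}

as_state_vector <- function(state) {
  if (inherits(state, "population_state")) return(unclass(state))
  y <- as.numeric(state)
  if (length(y) == 2) y <- c(y, 0, 0)
  stopifnot(length(y) == 4)
  stats::setNames(y, c("A1", "M1", "A2", "M2"))
}

#' Derived totals of a state
#'
#' Totals are always recomputed from the compartments: the grand total
#' `N_T`, per-species totals, and (cheater variant) the cooperator total
#' `N_coop` that serves as the growth-rate reference.
#'
#' @param state a [population_state()] or length-4 numeric vector.
#' @return named list with `N_T`, `N_T1`, `N_T2`, `N_coop`.
#' @export
state_totals <- function(state) {
  y <- as_state_vector(state)
  list(N_T = sum(y), N_T1 = y[["A1"]] + y[["M1"]],
       N_T2 = y[["A2"]] + y[["M2"]], N_coop = y[["A1"]] + y[["M1"]])
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> t = %g\n", attr(x, "t")))
  print(unclass(x))
  invisible(x)
}

#' Initial state of the stress phase
#'
#' Implements the convention that simulations start at stress onset with the
#' ancestor at its deterministic pre-stress equilibrium: carrying capacity
#' `K` for single-species variants; for mutualism the pre-stress total
#' (`K` with shared resources, `2 K` without) split
#' `initial_fraction : 1 - initial_fraction` between the two species. The
#' cheater variant instead returns the configured burn-in starting point
#' (cooperators at `N_c`, cheaters at `N_c / 10` by default); the burn-in
#' itself is run by [run_simulation()].
#'
#' @param p a [rescue_params()] object.
#' @return a [population_state()].
#' @export
initial_state <- function(p) {
  validate_params(p)
  f <- p$initial_fraction
  switch(p$model_variant,
    baseline = ,
    cooperation = population_state(A1 = p$K),
    mutualism = population_state(A1 = f * p$K, A2 = (1 - f) * p$K),
    mutualism_no_competition =
      population_state(A1 = f * 2 * p$K, A2 = (1 - f) * 2 * p$K),
    cheater = population_state(A1 = p$burn_in_start[["coop"]],
                               A2 = p$burn_in_start[["cheat"]],
                               t = -p$burn_in))
}
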