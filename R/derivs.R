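#' Deterministic derivatives of a model variant
#'
#' Right-hand side of the ordinary differential equations governing one
#' model variant, evaluated at a state. Every compartment follows
#' `growth_rate(reference) * N * (1 - crowding / K) - delta * N`, where the
#' growth-rate reference and the crowding total depend on the variant:
#'
#' * `baseline` / `cooperation`: reference and crowding are the species' own
#'   total `N_T = A + M`; the baseline has no Allee reduction.
#' * `mutualism`: each species' reference is its *partner's* total; crowding
#'   uses the grand total of both species (shared resources).
#' * `mutualism_no_competition`: as mutualism but each species is crowded
#'   only by itself.
#' * `cheater`: the reference is the cooperator total `N_coop`; cooperators
#'   follow the usual response while cheaters grow at `r (1 + b)` above
#'   `N_c` and `r (1 - rho)(1 - a)` below; crowding uses the grand total.
#'
#' A compartment at zero abundance always has zero derivative: nothing is
#' spontaneously generated outside the mutation operator.
#'
#' @param state a [population_state()] or length-4 numeric `c(A1, M1, A2, M2)`.
#' @param p a [rescue_params()] object.
#' @param delta death rate override (defaults to `p$delta`); the burn-in
#'   phase of the cheater model uses `p$burn_in_delta`.
#' @param force_full_mutant logical vector of length 2; where `TRUE`, the
#'   corresponding species' mutant compartment uses the above-threshold
#'   growth rate regardless of the reference density. Used by the analytic
#'   rescue-window machinery, which tracks mutant growth inside the window
#'   where the threshold condition holds by construction.
#' @return named numeric vector of derivatives `c(A1, M1, A2, M2)`.
#' @examples
#' p <- rescue_params("cooperation", r_A = 1, K = 1000, N_c = 50,
#'                    rho = 0.5, delta = 1.5)
#' model_derivatives(c(100, 0, 0, 0), p)  # dA1/dt = -60
#' @export
model_derivatives <- function(state, p, delta = p$delta,
                              force_full_mutant = c(FALSE, FALSE)) {
  y <- as_state_vector(state)
  A1 <- y[["A1"]]; M1 <- y[["M1"]]; A2 <- y[["A2"]]; M2 <- y[["M2"]]
  NT1 <- A1 + M1; NT2 <- A2 + M2; NT <- NT1 + NT2
  lo <- 1 - p$rho
  r_A <- rep_len(p$r_A, 2L); r_M <- rep_len(p$r_M, 2L)
  ffm <- rep_len(force_full_mutant, 2L)

  d <- switch(p$model_variant,
    baseline = {
      logi <- 1 - NT1 / p$K
      c(r_A[1] * A1 * logi - delta * A1,
        r_M[1] * M1 * logi - delta * M1, 0, 0)
    },
    cooperation = {
      f <- allee_multiplier(p, 1, lo, NT1)
      fM <- if (ffm[1]) 1 else f
      logi <- 1 - NT1 / p$K
      c(r_A[1] * f * A1 * logi - delta * A1,
        r_M[1] * fM * M1 * logi - delta * M1, 0, 0)
    },
    mutualism = ,
    mutualism_no_competition = {
      f1 <- allee_multiplier(p, 1, lo, NT2)  # species 1 looks at partner
      f2 <- allee_multiplier(p, 1, lo, NT1)
      if (p$model_variant == "mutualism") {
        logi1 <- 1 - NT / p$K; logi2 <- logi1
      } else {
        logi1 <- 1 - NT1 / p$K; logi2 <- 1 - NT2 / p$K
      }
      f1M <- if (ffm[1]) 1 else f1
      f2M <- if (ffm[2]) 1 else f2
      c(r_A[1] * f1 * A1 * logi1 - delta * A1,
        r_M[1] * f1M * M1 * logi1 - delta * M1,
        r_A[2] * f2 * A2 * logi2 - delta * A2,
        r_M[2] * f2M * M2 * logi2 - delta * M2)
    },
    cheater = {
      N_coop <- NT1
      fc <- allee_multiplier(p, 1, lo, N_coop)
      fcM <- if (ffm[1]) 1 else fc
      fq <- allee_multiplier(p, 1 + p$b, lo * (1 - p$a), N_coop)
      logi <- 1 - NT / p$K
      c(r_A[1] * fc * A1 * logi - delta * A1,
        r_M[1] * fcM * M1 * logi - delta * M1,
        r_A[2] * fq * A2 * logi - delta * A2,
        r_M[2] * fq * M2 * logi - delta * M2)
    })
  stats::setNames(d, c("A1", "M1", "A2", "M2"))
}
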