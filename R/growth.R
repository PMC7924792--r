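#' Step (strong Allee) growth-rate response
#'
#' The per-capita exponential growth rate as a function of the reference
#' density: the full rate `r` when the reference exceeds the critical
#' population size, and the reduced rate `r (1 - rho)` at or below it
#' (strict `>` keeps the high branch, so exact equality gets the reduced
#' rate).
#'
#' @param r full growth rate (`>= 0`).
#' @param N_ref reference density the response is evaluated at (the total
#'   population for cooperation, the partner total for mutualism, the
#'   cooperator total for the cheater model).
#' @param N_c critical population size.
#' @param rho Allee depth in `[0, 1]`.
#' @return the effective growth rate (vectorized over `N_ref`).
#' @examples
#' growth_rate_step(1, N_ref = 150, N_c = 100, rho = 0.9)  # 1
#' growth_rate_step(1, N_ref = 50, N_c = 100, rho = 0.9)   # 0.1
#' @export
growth_rate_step <- function(r, N_ref, N_c, rho) {
  if (any(r < 0) || any(N_ref < 0) || N_c < 0)
    stop("negative inputs are not allowed", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  ifelse(N_ref > N_c, r, r * (1 - rho))
}

#' Smooth (Hill-type) growth-rate response
#'
#' A continuous, monotonically non-decreasing alternative to the step
#' response: `r (1 - rho * N_c^h / (N_c^h + N_ref^h))`. It tends to
#' `r (1 - rho)` as `N_ref -> 0`, to `r` as `N_ref -> Inf`, equals the
#' midpoint `r (1 - rho / 2)` at `N_ref = N_c`, and converges pointwise
#' (away from `N_c`) to [growth_rate_step()] as `h -> Inf`.
#'
#' @inheritParams growth_rate_step
#' @param h Hill steepness, `> 0`.
#' @return the effective growth rate (vectorized over `N_ref`).
#' @examples
#' growth_rate_smooth(1, N_ref = 100, N_c = 100, rho = 0.8, h = 4)  # 0.6
#' @export
growth_rate_smooth <- function(r, N_ref, N_c, rho, h) {
  if (any(r < 0) || any(N_ref < 0) || N_c < 0)
    stop("negative inputs are not allowed", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  if (h <= 0) stop("steepness h must be > 0", call. = FALSE)
  s <- hill_weight(N_ref, N_c, h)
  r * (1 - rho * (1 - s))
}

# weight of the above-threshold branch: N_ref^h / (N_c^h + N_ref^h),
# computed on the log scale to survive large h
hill_weight <- function(N_ref, N_c, h) {
  if (N_c <= 0) return(rep_len(1, length(N_ref)))
  s <- numeric(length(N_ref))
  pos <- N_ref > 0
  lr <- h * (log(N_ref[pos]) - log(N_c))
  s[pos] <- ifelse(lr > 700, 1, ifelse(lr < -700, 0, exp(lr) / (1 + exp(lr))))
  s
}

# dispatches on the configured Allee form; hi/lo are the two branch
# multipliers (cooperators: 1 and 1 - rho; cheaters: 1 + b and
# (1 - rho)(1 - a))
allee_multiplier <- function(p, hi, lo, N_ref) {
  if (p$allee_form == "step") {
    ifelse(N_ref > p$N_c, hi, lo)
  } else {
    s <- hill_weight(N_ref, p$N_c, p$smooth_steepness)
    hi * s + lo * (1 - s)
  }
}
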