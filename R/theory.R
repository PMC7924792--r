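# Analytic rescue-time-window theory. All first-passage times are computed
# on the deterministic flow by dense-output integration plus root finding
# (deSolve::lsodar); closed-form exponential/logistic formulas serve as test
# oracles only. The state is augmented with running integrals of the two
# ancestor compartments so that mutant-arrival integrals come out of the
# same solve.

# deSolve right-hand side; y = c(A1, M1, A2, M2, intA1, intA2)
flow_rhs <- function(t, y, parms) {
  d <- model_derivatives(y[1:4], parms$p, parms$delta, parms$ffm)
  list(c(d, y[1], y[3]))
}

flow_pars <- function(p, delta = p$delta, ffm = c(FALSE, FALSE)) {
  list(p = p, delta = delta, ffm = ffm)
}

aug_state <- function(y) c(as_state_vector(y), intA1 = 0, intA2 = 0)

# plain solve at requested times
flow_solve <- function(y0, parms, times, rtol = 1e-10, atol = 1e-8) {
  deSolve::lsoda(y = y0, times = times, func = flow_rhs, parms = parms,
                 rtol = rtol, atol = atol, maxsteps = 50000)
}

# step-response branch-crossing levels watched during integration, so that
# each solve segment has a smooth right-hand side (integration restarts at
# every crossing)
crossing_funs <- function(p) {
  if (p$allee_form == "smooth" || p$rho == 0 || p$N_c <= 0) return(list())
  switch(p$model_variant,
    baseline = list(),
    cooperation = list(function(y) y[1] + y[2] - p$N_c),
    mutualism = ,
    mutualism_no_competition =
      list(function(y) y[1] + y[2] - p$N_c,
           function(y) y[3] + y[4] - p$N_c),
    cheater = list(function(y) y[1] + y[2] - p$N_c))
}

# integrates from t0 until one of the stop functions crosses zero; the
# step-response branch crossings are watched too, and integration restarts
# there so every solver segment sees a smooth right-hand side. Returns
# list(t, y, which) giving the index of the stop function that fired, or
# NULL if none fires before `horizon`.
flow_to_event <- function(y0, parms, t0, horizon, stop_funs,
                          rtol = 1e-10, atol = 1e-8) {
  if (is.function(stop_funs)) stop_funs <- list(stop_funs)
  n_stop <- length(stop_funs)
  cross <- crossing_funs(parms$p)
  rootfun <- function(t, y, parms_)
    c(vapply(stop_funs, function(f) f(y), numeric(1)),
      vapply(cross, function(f) f(y), numeric(1)))
  t <- t0; y <- y0
  for (seg in 1:60) {
    res <- deSolve::lsodar(y = y, times = c(t, horizon), func = flow_rhs,
                           parms = parms, rootfunc = rootfun,
                           rtol = rtol, atol = atol, maxsteps = 50000)
    troot <- attr(res, "troot")
    last <- res[nrow(res), -1]
    if (length(troot) == 0 || is.na(troot[1])) return(NULL)
    fired <- which(attr(res, "iroot") == 1)
    hit <- fired[fired <= n_stop]
    if (length(hit) > 0)
      return(list(t = troot[1], y = as.numeric(last), which = min(hit)))
    # a branch crossing fired: restart the solver there
    t <- troot[1]; y <- as.numeric(last)
    names(y) <- names(y0)
    if (t >= horizon) return(NULL)
  }
  stop("integrator failure: too many branch crossings", call. = FALSE)
}

# generous horizon for decline solves (closed-form bound where finite)
decline_horizon <- function(p, N0, K_eff, N_target) {
  cand <- c(decline_time_closed(max(p$r_A), p$rho, p$delta, K_eff, p$N_c,
                                N0, N_target),
            decline_time_closed(max(p$r_A), 0, p$delta, K_eff, p$N_c,
                                N0, N_target))
  fin <- cand[is.finite(cand)]
  if (length(fin) == 0) 400 else max(4 * max(fin), 10)
}

# per-variant geometry of the ancestor-only decline problem
decline_setup <- function(p) {
  switch(p$model_variant,
    baseline = ,
    cooperation = list(y0 = aug_state(initial_state(p)), N0 = p$K,
                       K_eff = p$K),
    mutualism = list(y0 = aug_state(initial_state(p)),
                     N0 = max(p$initial_fraction, 1 - p$initial_fraction)
                          * p$K,
                     K_eff = p$K / 2),
    mutualism_no_competition =
      list(y0 = aug_state(initial_state(p)),
           N0 = max(p$initial_fraction, 1 - p$initial_fraction) * 2 * p$K,
           K_eff = p$K),
    cheater = stop("the analytic theory does not cover the cheater variant",
                   call. = FALSE))
}

#' Time for the ancestral population to decline to a target size
#'
#' First-passage time of the deterministic (mutation-free) ancestor flow
#' from its initial size to `N_target`, computed by dense-output integration
#' with root finding; the piecewise branch switch of the step Allee response
#' at `N_c` is handled by restarting the solver at each crossing. The
#' species-1 total is the reference that must reach the target (for the
#' symmetric mutualism variants both species cross together).
#'
#' @param p a [rescue_params()] object (not the cheater variant).
#' @param N_start optional override of the initial species-1 abundance
#'   (two-species variants start both species at `N_start`).
#' @param N_target target size; defaults to `max(N_c, extinction_threshold)`.
#' @return the first-passage time (0 when `N_target >= N_start`).
#' @export
ancestor_decline_time <- function(p, N_start = NULL, N_target = NULL) {
  validate_params(p)
  setup <- decline_setup(p)
  y0 <- setup$y0
  if (!is.null(N_start)) {
    y0[1] <- N_start
    if (length(species_labels(p)) == 2) y0[3] <- N_start
    setup$N0 <- N_start
  }
  if (is.null(N_target)) N_target <- max(p$N_c, p$extinction_threshold)
  if (N_target >= y0[1]) return(0)
  horizon <- decline_horizon(p, setup$N0, setup$K_eff, N_target)
  ev <- flow_to_event(y0, flow_pars(p), t0 = 0, horizon = horizon,
                      stop_funs = function(y) y[1] + y[2] - N_target)
  if (is.null(ev))
    stop("no finite decline time: the ancestor does not reach the target ",
         "under these parameters", call. = FALSE)
  ev$t
}

# shared machinery: latest viable mutant-arrival time (the rescue window)
# for cooperation/baseline and the mutualism variants. A mutant seeded with
# one extinction-threshold unit at time tau grows with the above-threshold
# rate (inside the window the threshold condition holds by construction)
# against the declining background, the background itself following its
# actual branch rates; the window is the largest tau for which the mutant
# reaches the critical size by the time the ancestor total does.
window_coupled <- function(p) {
  thr <- p$extinction_threshold
  target <- max(p$N_c, thr)
  if (min(p$r_M) <= p$delta)
    stop("mutant cannot grow: r_M <= delta", call. = FALSE)
  t_dec <- ancestor_decline_time(p, N_target = target)
  if (target <= thr)   # no Allee barrier: any arrival counts immediately
    return(list(t_decline = t_dec, t_grow = 0, window = t_dec,
                arrival_start = 0))

  edges <- arrival_edges(p, background_flow(decline_setup(p)$y0,
                                            flow_pars(p), t_dec),
                         parms_dyn = flow_pars(p), comp = 2L,
                         bracket_hi = t_dec, target = target)
  if (is.null(edges)) {
    r0 <- forced_reach_time(p, 0)
    return(list(t_decline = t_dec, t_grow = max(r0, t_dec), window = 0,
                arrival_start = 0))
  }
  list(t_decline = t_dec, t_grow = t_dec - edges[2], window = edges[2],
       arrival_start = edges[1])
}

# dense ancestor-background flow on [0, t_end]; returns state interpolation
# plus the cumulative ancestor integrals
background_flow <- function(y0, parms, t_end, events = NULL) {
  times <- seq(0, max(t_end, 1e-8), length.out = 400)
  if (!is.null(events))  # deSolve wants event times among the output times
    times <- sort(unique(c(times, events$data$time)))
  out <- if (is.null(events))
    flow_solve(y0, parms, times)
  else
    deSolve::lsoda(y = y0, times = times, func = flow_rhs, parms = parms,
                   rtol = 1e-10, atol = 1e-8, maxsteps = 50000,
                   events = events)
  nm <- names(y0)
  state_at <- function(tau) {
    i <- max(which(out[, "time"] <= tau + 1e-12))
    y <- as.numeric(out[i, -1])
    t0 <- out[i, "time"]
    if (tau > t0 + 1e-12) {
      ref <- flow_solve(stats::setNames(y, nm), parms, c(t0, tau))
      y <- as.numeric(ref[nrow(ref), -1])
    }
    stats::setNames(y, nm)
  }
  list(state_at = state_at,
       C1 = stats::approxfun(out[, "time"], out[, "intA1"], rule = 2),
       C2 = stats::approxfun(out[, "time"], out[, "intA2"], rule = 2),
       sol = out)
}

# can a mutant seeded at time tau establish and reach the target? The seed
# (one extinction-threshold unit, added to compartment `comp` on the
# background flow) wins if it reaches `target` before dipping back below
# the threshold -- the dip emulates the simulation's extinction clamp, and
# is what kills arrivals during the early phase when logistic crowding
# makes the mutant's net growth rate negative. Extra failure conditions
# (e.g. partner collapse) can be supplied.
seed_viable <- function(p, bg, parms_dyn, comp, tau, target,
                        extra_fail = list()) {
  thr <- p$extinction_threshold
  y <- bg$state_at(tau)
  y[comp] <- y[comp] + thr
  grow_bound <- 8 * log(target / thr) / (min(p$r_M) - p$delta) + 10
  stops <- c(list(function(yy) yy[comp] - target,
                  function(yy) yy[comp] - thr * (1 - 1e-7)),
             extra_fail)
  ev <- flow_to_event(y, parms_dyn, t0 = tau, horizon = tau + grow_bound,
                      stop_funs = stops)
  !is.null(ev) && ev$which == 1
}

# interval [tau_lo, tau_hi] of arrival times from which a seeded mutant
# establishes, found by scanning for one viable time and bisecting both
# edges; NULL when no arrival time is viable
arrival_edges <- function(p, bg, parms_dyn, comp, bracket_hi, target,
                          extra_fail = list()) {
  v <- function(tau) seed_viable(p, bg, parms_dyn, comp, tau, target,
                                 extra_fail)
  fr <- c(0.5, 0.25, 0.75, 0.1, 0.9, 0.04, 0.6, 0.35, 0.96, 0.02)
  seed <- NA_real_
  for (f in fr) {
    tau <- f * bracket_hi
    if (v(tau)) { seed <- tau; break }
  }
  if (is.na(seed)) return(NULL)
  tol <- 1e-3 * max(1, bracket_hi)
  # lower edge
  if (v(0)) {
    tau_lo <- 0
  } else {
    lo <- 0; hi <- seed
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (v(mid)) hi <- mid else lo <- mid
    }
    tau_lo <- hi
  }
  # upper edge
  hi_end <- bracket_hi * (1 - 1e-9)
  if (v(hi_end)) {
    tau_hi <- bracket_hi
  } else {
    lo <- seed; hi <- hi_end
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (v(mid)) lo <- mid else hi <- mid
    }
    tau_hi <- lo
  }
  c(tau_lo, tau_hi)
}

# the interval of arrival times over which a mutant establishes, for the
# arrival-probability integral. For the baseline variant the late edge is
# the ancestor extinction time (no Allee deadline); the early edge is still
# set by logistic crowding at stress onset. NULL when no arrival can
# establish.
effective_arrival_window <- function(p) {
  thr <- p$extinction_threshold
  target <- max(p$N_c, thr)
  if (p$model_variant == "baseline") {
    t_dec <- ancestor_decline_time(p, N_target = thr)
    if (target <= thr) return(list(tau_lo = 0, tau_hi = t_dec))
    bg <- background_flow(decline_setup(p)$y0, flow_pars(p), t_dec)
    edges <- arrival_edges(p, bg, parms_dyn = flow_pars(p), comp = 2L,
                           bracket_hi = t_dec, target = target)
    if (is.null(edges)) return(NULL)
    return(list(tau_lo = edges[1], tau_hi = edges[2]))
  }
  w <- window_coupled(p)
  if (w$window <= 0) return(NULL)
  list(tau_lo = w$arrival_start, tau_hi = w$window)
}

# forced-growth reach time from arrival tau, assuming the above-threshold
# rate throughout (diagnostic for zero-window reporting)
forced_reach_time <- function(p, tau) {
  thr <- p$extinction_threshold
  target <- max(p$N_c, thr)
  y_init <- decline_setup(p)$y0
  y <- if (tau > 0) {
    out <- flow_solve(y_init, flow_pars(p), c(0, tau))
    stats::setNames(as.numeric(out[nrow(out), -1]), names(y_init))
  } else y_init
  y[2] <- y[2] + thr
  grow_bound <- 8 * log(target / thr) / (min(p$r_M) - p$delta) + 10
  ev <- flow_to_event(y, flow_pars(p, ffm = c(TRUE, FALSE)), t0 = tau,
                      horizon = tau + grow_bound,
                      stop_funs = function(yy) yy[2] - target)
  if (is.null(ev)) Inf else ev$t
}

#' Time for a mutant to grow to the critical population size
#'
#' Deterministic time for a mutant lineage, seeded at the extinction
#' threshold, to grow to `N_c`. The default (`"coupled"`) evaluates the
#' logistic crowding term on the declining ancestor background, seeding the
#' mutant at the marginal arrival time so that it reaches `N_c` exactly when
#' the ancestor total does; `"bare"` is the documented fast approximation
#' `log(N_c / threshold) / (r_M - delta)` that ignores crowding.
#'
#' @param p a [rescue_params()] object.
#' @param method `"coupled"` (default) or `"bare"`.
#' @return the growth time (possibly `Inf` when crowding prevents the mutant
#'   from ever reaching `N_c`); 0 when `N_c` is at or below the extinction
#'   threshold.
#' @export
mutant_growth_time <- function(p, method = c("coupled", "bare")) {
  validate_params(p)
  method <- match.arg(method)
  thr <- p$extinction_threshold
  target <- max(p$N_c, thr)
  if (target <= thr) return(0)
  if (min(p$r_M) <= p$delta)
    stop("mutant cannot grow: r_M <= delta", call. = FALSE)
  if (method == "bare") return(log(target / thr) / (min(p$r_M) - p$delta))
  window_coupled(p)$t_grow
}

#' Analytic rescue time window
#'
#' The interval after stress onset during which a newly arisen mutant can
#' still reach the critical population size before the ancestor total falls
#' below it: `window = max(0, t_decline - t_grow)`. For the baseline (no
#' Allee effect) variant the window is the full ancestor extinction time,
#' since an established mutant spreads regardless of total population size.
#'
#' @param p a [rescue_params()] object (cooperation, baseline, or mutualism
#'   variants).
#' @return an object of class `rescue_window`: list with `t_decline`,
#'   `t_grow`, `window`.
#' @examples
#' rescue_window(rescue_params("cooperation", N_c = 50))
#' @export
rescue_window <- function(p) {
  validate_params(p)
  w <- if (p$model_variant == "baseline") {
    t_ext <- ancestor_decline_time(p, N_target = p$extinction_threshold)
    list(t_decline = t_ext, t_grow = 0, window = t_ext)
  } else {
    window_coupled(p)
  }
  structure(w, class = "rescue_window")
}

#' @export
print.rescue_window <- function(x, ...) {
  cat(sprintf(
    "<rescue_window> decline %.4g, mutant growth %.4g, window %.4g\n",
    x$t_decline, x$t_grow, x$window))
  invisible(x)
}

#' Closed-form approximation of the rescue probability
#'
#' The probability that an adapted mutant arises during the rescue time
#' window, under the Poisson arrival model: for cooperation and baseline,
#' `P = 1 - exp(-mu * I)` with `I` the integral of the deterministic
#' ancestor trajectory over the window. For mutualism without interspecies
#' competition the two species adapt independently and `P` is the product of
#' the two single-species probabilities (the square, when symmetric). For
#' mutualism with competition, `P` is the product of the first species'
#' arrival probability and the second species' arrival probability over a
#' truncated window: the partner's decline is recomputed with the adapted
#' competitor's deterministic growth included (seeded at the conditional
#' median arrival time), and the second window ends at the latest arrival
#' for which the second mutant still reaches `N_c` before its species total
#' falls below `N_c`.
#'
#' @param p a [rescue_params()] object; the cheater variant is not supported
#'   (no closed form exists).
#' @return the approximate rescue probability.
#' @examples
#' rescue_probability_theory(rescue_params("cooperation", N_c = 50))
#' @export
rescue_probability_theory <- function(p) {
  validate_params(p)
  if (p$model_variant == "cheater")
    stop("rescue_probability_theory does not support the cheater variant",
         call. = FALSE)
  if (all(p$mu == 0)) return(0)
  thr <- p$extinction_threshold
  target <- max(p$N_c, thr)

  if (p$model_variant %in% c("baseline", "cooperation")) {
    eff <- effective_arrival_window(p)
    if (is.null(eff) || eff$tau_hi <= eff$tau_lo) return(0)
    bg <- background_flow(decline_setup(p)$y0, flow_pars(p), eff$tau_hi)
    return(1 - exp(-p$mu[1] * (bg$C1(eff$tau_hi) - bg$C1(eff$tau_lo))))
  }

  if (p$model_variant == "mutualism_no_competition") {
    # independent species: product of single-population probabilities
    ps <- vapply(1:2, function(i) {
      pi <- rescue_params("cooperation", r_A = rep_len(p$r_A, 2)[i],
                          r_M = rep_len(p$r_M, 2)[i], K = p$K, N_c = p$N_c,
                          rho = p$rho, delta = p$delta,
                          mu = rep_len(p$mu, 2)[i],
                          allee_form = p$allee_form,
                          smooth_steepness = p$smooth_steepness,
                          dt = p$dt,
                          extinction_threshold = p$extinction_threshold)
      rescue_probability_theory(pi)
    }, numeric(1))
    return(prod(ps))
  }

  # mutualism with competition
  mu <- rep_len(p$mu, 2L)
  eff <- effective_arrival_window(p)
  if (is.null(eff) || eff$tau_hi <= eff$tau_lo) return(0)
  y0 <- decline_setup(p)$y0
  bg1 <- background_flow(y0, flow_pars(p), eff$tau_hi)
  L1 <- function(t) mu[1] * (bg1$C1(t) - bg1$C1(eff$tau_lo))
  P1 <- 1 - exp(-L1(eff$tau_hi))
  if (P1 <= 0) return(0)

  # conditional median first-arrival time of the first adapting species
  target_L <- -log(1 - 0.5 * P1)
  t_bar <- if (L1(eff$tau_hi) <= target_L) eff$tau_hi else
    uniroot(function(t) L1(t) - target_L, c(eff$tau_lo, eff$tau_hi),
            tol = 1e-6 * max(1, eff$tau_hi))$root

  # background with the first species' mutant established at t_bar and held
  # on its adapted course; the second species' ancestors decline faster
  # under the added competition, truncating its arrival window
  parms_bg2 <- flow_pars(p, ffm = c(TRUE, FALSE))
  ev_seed <- list(data = data.frame(var = "M1", time = t_bar,
                                    value = thr, method = "add"))
  horizon <- decline_horizon(p, p$K / 2, p$K / 2, thr) + t_bar + 10
  bg2 <- background_flow(y0, parms_bg2, horizon, events = ev_seed)
  # arrivals in species 2 are only possible while its ancestors persist
  a2_end <- {
    a2 <- bg2$sol[, "A2"]
    tt <- bg2$sol[, "time"]
    if (any(a2 < thr)) tt[min(which(a2 < thr))] else horizon
  }
  edges2 <- arrival_edges(
    p, bg2, parms_dyn = parms_bg2, comp = 4L, bracket_hi = a2_end,
    target = target,
    extra_fail = list(function(yy) (yy[3] + yy[4]) - target))
  if (is.null(edges2)) return(0)
  L2 <- mu[2] * (bg2$C2(edges2[2]) - bg2$C2(edges2[1]))
  P1 * (1 - exp(-L2))
}

#' Rescue window and probability over a parameter grid
#'
#' Evaluates [rescue_window()] and [rescue_probability_theory()] on every
#' row of a grid of parameter overrides, for CSV export of window /
#' probability surfaces.
#'
#' @param base_params a [rescue_params()] object giving the fixed values.
#' @param grid data frame whose columns name parameters to override (e.g.
#'   `N_c`, `mu`, `delta`, `r_M`).
#' @return data frame: the grid columns plus `t_decline`, `t_grow`,
#'   `window`, `p_theory`.
#' @export
theory_surface <- function(base_params, grid) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- do.call(update_params,
                 c(list(base_params), as.list(grid[i, , drop = FALSE])))
    w <- rescue_window(p)
    data.frame(grid[i, , drop = FALSE],
               t_decline = w$t_decline, t_grow = w$t_grow,
               window = w$window,
               p_theory = rescue_probability_theory(p),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced and re-validated.
#'
#' @param p a [rescue_params()] object.
#' @param ... named fields to replace (any [rescue_params()] argument).
#' @return a [rescue_params()] object.
#' @export
update_params <- function(p, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(p)
  x <- params_to_list(p)
  unknown <- setdiff(names(repl), .param_keys)
  if (length(unknown) > 0)
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params_from_list(modifyList(x, repl))
}
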