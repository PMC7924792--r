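test_that("mutant arrivals are Poisson with mean mu * A * dt", {
  expect_equal(sample_mutants(rep(1e6, 50), mu = 0, dt = 0.01), rep(0L, 50))
  expect_equal(sample_mutants(rep(0, 50), mu = 1e-3, dt = 0.01), rep(0L, 50))
  expect_error(sample_mutants(-1, 1e-3, 0.01), "non-negative")
  set.seed(99)
  draws <- sample_mutants(rep(1e6, 1e5), mu = 1e-6, dt = 0.01)
  # law of large numbers: sample mean within 3 SE of 0.01; variance ~ mean
  se <- sqrt(0.01 / 1e5)
  expect_lt(abs(mean(draws) - 0.01), 3 * se)
  expect_lt(abs(var(draws) - 0.01), 5 * se)
})

test_that("a mutation-free step is deterministic and respects equilibria", {
  p <- rescue_params("cooperation", mu = 0)
  s0 <- initial_state(p)
  set.seed(1); s1 <- step_state(s0, p)
  set.seed(2); s2 <- step_state(s0, p)
  expect_identical(unclass(s1), unclass(s2))
  # logistic equilibrium with no stress stays put
  p0 <- update_params(p, delta = 0)
  s <- step_state(population_state(A1 = p0$K), p0, delta = 0)
  expect_equal(s[["A1"]], p0$K, tolerance = 1e-9)
  expect_equal(attr(s, "t"), p0$dt)
})

test_that("one interval of pure decline matches the exponential solution", {
  # logistic term ~ 1 and no Allee branch: dA/dt = (r - delta) A
  p <- rescue_params("cooperation", r_A = 1, r_M = 2, delta = 2, K = 1e12,
                     N_c = 0, mu = 0)
  s <- step_state(population_state(A1 = 1000), p)
  expect_equal(s[["A1"]], 1000 * exp(-0.01), tolerance = 1e-9)
})

test_that("identical (params, seed) give bit-identical outcomes", {
  p <- rescue_params("cooperation", mu = 1e-3)
  o1 <- run_simulation(p, seed = 7)
  o2 <- run_simulation(p, seed = 7)
  expect_identical(o1$verdict, o2$verdict)
  expect_identical(o1$mutation_events, o2$mutation_events)
  expect_identical(unclass(o1$final_state), unclass(o2$final_state))
  expect_identical(o1$trajectory, o2$trajectory)
})

test_that("verdicts cover deterministic extinction, no-stress, and
           saturation rescue", {
  # mu = 0 under stress: extinct at finite time
  o <- run_simulation(rescue_params("cooperation", mu = 0), seed = 1,
                      record_stride = 0L)
  expect_equal(o$verdict, "extinct")
  expect_true(is.finite(o$verdict_time))
  expect_true(all(unclass(o$final_state) == 0))
  # no stress: no extinction, undecided at the horizon
  o2 <- run_simulation(rescue_params("cooperation", delta = 0, mu = 0,
                                     t_max = 5), seed = 1,
                       record_stride = 0L)
  expect_equal(o2$verdict, "undecided_at_t_max")
  # saturated mutation supply: essentially certain rescue
  p3 <- rescue_params("cooperation", mu = 0.05, N_c = 10)
  expect_equal(rescue_fraction(p3, 100, 500), 1)
})

test_that("trajectories are non-negative, clamped, and tidy on export", {
  p <- rescue_params("cooperation", mu = 1e-3)
  o <- run_simulation(p, seed = 11)
  tr <- o$trajectory
  expect_true(all(tr[, -1] >= 0))
  # no abundance strictly between 0 and the extinction threshold at
  # recorded interval boundaries
  vals <- unlist(tr[, c("A1", "M1")])
  expect_true(all(vals == 0 | vals >= p$extinction_threshold - 1e-9))
  td <- trajectory_df(o)
  expect_named(td, c("t", "species", "genotype", "abundance"))
  expect_setequal(unique(td$genotype), c("ancestor", "mutant"))
  expect_equal(nrow(td), 2 * nrow(tr))
})

test_that("mu = 0 trajectories match the closed-form logistic-with-death
           solution", {
  p <- rescue_params("baseline", r_A = 1, delta = 1.1, K = 1000, mu = 0,
                     t_max = 4)
  o <- run_simulation(p, seed = 1)
  tr <- o$trajectory
  keep <- tr$A1 > 0
  expected <- oracle_trajectory(1, 1.1, 1000, 1000, tr$t[keep])
  expect_equal(tr$A1[keep], expected, tolerance = 1e-6)
})

test_that("cooperation rescue requires a mutation before the ancestors
           are below the critical size", {
  p <- rescue_params("cooperation", mu = 3e-4)
  t_cross <- ancestor_decline_time(p, N_target = p$N_c)
  for (i in 1:60) {
    o <- run_simulation(p, seed = 3000 + i, record_stride = 0L)
    if (o$verdict == "rescued") {
      expect_true(any(o$mutation_events$time <= t_cross))
    }
  }
})

test_that("the cheater burn-in oscillates around the critical size", {
  p <- rescue_params("cheater", mu = 0, burn_in = 100)
  o <- run_simulation(p, seed = 1, record_stride = 5L)
  burn <- o$trajectory[o$trajectory$t <= 0, ]
  n_coop <- burn$A1 + burn$M1
  crossings <- sum(diff(sign(n_coop - p$N_c)) != 0)
  expect_gte(crossings, 2)
  # stress onset is at t = 0, burn-in times are negative
  expect_lt(min(burn$t), 0)
  expect_equal(max(o$trajectory$t) >= 0, TRUE)
})

test_that("outcome JSON round-trips the verdict and parameters", {
  o <- run_simulation(rescue_params("cooperation", mu = 1e-3), seed = 3,
                      record_stride = 0L)
  js <- jsonlite::fromJSON(outcome_to_json(o))
  expect_equal(js$verdict, o$verdict)
  expect_equal(js$params$model_variant, "cooperation")
  expect_equal(js$seed, 3)
})
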