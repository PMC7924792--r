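test_that("step growth-rate response follows the two-branch rule", {
  expect_equal(growth_rate_step(1, N_ref = 150, N_c = 100, rho = 0.9), 1)
  expect_equal(growth_rate_step(1, N_ref = 50, N_c = 100, rho = 0.9), 0.1)
  expect_equal(growth_rate_step(0.7, N_ref = 12345, N_c = 100, rho = 0), 0.7)
  # equality at the threshold takes the reduced branch (strict '>')
  expect_equal(growth_rate_step(1, N_ref = 100, N_c = 100, rho = 0.4), 0.6)
  expect_error(growth_rate_step(-1, 10, 100, 0.5), "negative")
  expect_error(growth_rate_step(1, 10, 100, 1.5), "rho")
})

test_that("smooth growth-rate response has the right limits and midpoint", {
  expect_equal(growth_rate_smooth(1, N_ref = 100, N_c = 100, rho = 0.8,
                                  h = 4), 0.6)
  expect_equal(growth_rate_smooth(1, N_ref = 0, N_c = 100, rho = 0.8,
                                  h = 4), 0.2)
  expect_equal(growth_rate_smooth(1, N_ref = 1e9, N_c = 100, rho = 0.8,
                                  h = 4), 1, tolerance = 1e-6)
  expect_equal(growth_rate_smooth(1, N_ref = 77, N_c = 100, rho = 0, h = 2),
               1)
  expect_error(growth_rate_smooth(1, 10, 100, 0.5, h = 0), "h")
  # monotone non-decreasing in the reference density
  v <- growth_rate_smooth(1, N_ref = seq(0, 400, by = 5), N_c = 100,
                          rho = 0.8, h = 4)
  expect_true(all(diff(v) >= 0))
  # pointwise convergence to the step form away from N_c as h grows
  for (N_ref in c(30, 85, 120, 300)) {
    expect_equal(growth_rate_smooth(1, N_ref, 100, 0.8, h = 5000),
                 growth_rate_step(1, N_ref, 100, 0.8), tolerance = 1e-6)
  }
})

test_that("cooperation derivatives match hand-computed values", {
  p <- rescue_params("cooperation", r_A = 1, K = 1000, N_c = 50, rho = 0.5,
                     delta = 1.5)
  # logistic equilibrium with no death
  p0 <- update_params(p, delta = 0)
  expect_equal(unname(model_derivatives(c(1000, 0, 0, 0), p0)),
               rep(0, 4))
  # above threshold: 1 * 100 * 0.9 - 1.5 * 100
  expect_equal(model_derivatives(c(100, 0, 0, 0), p)[["A1"]], -60)
  # below threshold: 0.5 * 40 * 0.96 - 1.5 * 40
  expect_equal(model_derivatives(c(40, 0, 0, 0), p)[["A1"]], -40.8)
})

test_that("mutualism derivatives use the partner reference and shared or
           per-species crowding", {
  p <- rescue_params("mutualism", r_A = 1, r_M = 2, K = 1000, N_c = 50,
                     rho = 0.5, delta = 0)
  d <- model_derivatives(c(200, 0, 30, 0), p)
  # species 1's partner (30) is below N_c, species 2's partner (200) above
  expect_equal(d[["A1"]], 0.5 * 200 * (1 - 230 / 1000))
  expect_equal(d[["A2"]], 1 * 30 * (1 - 230 / 1000))
  pn <- update_params(p, model_variant = "mutualism_no_competition")
  dn <- model_derivatives(c(200, 0, 30, 0), pn)
  expect_equal(dn[["A1"]], 0.5 * 200 * (1 - 200 / 1000))
  # symmetric state gives symmetric derivatives
  ds <- model_derivatives(c(300, 10, 300, 10), p)
  expect_equal(ds[["A1"]], ds[["A2"]])
  expect_equal(ds[["M1"]], ds[["M2"]])
})

test_that("cheater derivatives apply the two advantage factors", {
  p <- rescue_params("cheater", r_A = 1, r_M = 2, K = 1e9, N_c = 50,
                     rho = 0.5, delta = 0, a = 0.8, b = 0.5)
  # above N_c: cheater per-capita rate is (1+b) times the cooperator's
  d_hi <- model_derivatives(c(100, 0, 10, 0), p)
  expect_equal(d_hi[["A2"]] / 10, (1 + 0.5) * d_hi[["A1"]] / 100,
               tolerance = 1e-12)
  # below N_c: cheater multiplier is (1-a) times the cooperator's r(1-rho)
  d_lo <- model_derivatives(c(30, 0, 10, 0), p)
  expect_equal(d_lo[["A2"]] / 10, (1 - 0.8) * d_lo[["A1"]] / 30,
               tolerance = 1e-12)
  # a = b = 0: cheater and cooperator per-capita rates identical everywhere
  p00 <- update_params(p, a = 0, b = 0)
  for (coop in c(30, 100)) {
    d <- model_derivatives(c(coop, 0, 10, 0), p00)
    expect_equal(d[["A2"]] / 10, d[["A1"]] / coop, tolerance = 1e-12)
  }
})

test_that("zero compartments stay zero and rho=0, delta=0 reduces to
           logistic totals", {
  set.seed(5)
  for (v in c("baseline", "cooperation", "mutualism",
              "mutualism_no_competition", "cheater")) {
    p <- rescue_params(v, rho = 0, delta = 0, a = 0, b = 0, r_M = 1)
    for (k in 1:5) {
      y <- runif(4, 0, 500) * rbinom(4, 1, 0.7)
      if (length(species_labels(p)) == 1) y[3:4] <- 0
      d <- model_derivatives(y, p)
      expect_true(all(d[y == 0] == 0))
      # shared rate r = 1: total derivative is logistic in the grand total
      if (v != "mutualism_no_competition") {
        NT <- sum(y)
        expect_equal(sum(d), NT * (1 - NT / p$K), tolerance = 1e-9)
      }
    }
  }
})

test_that("compiled and R derivatives agree on random states", {
  set.seed(42)
  for (v in c("baseline", "cooperation", "mutualism",
              "mutualism_no_competition", "cheater")) {
    for (form in c("step", "smooth")) {
      p <- rescue_params(v, N_c = 40, allee_form = form, a = 0.7, b = 0.4)
      for (k in 1:10) {
        y <- runif(4, 0, 1200)
        expect_equal(
          unname(evorescue:::engine_rhs(y, evorescue:::pack_params(p),
                                        p$delta)),
          unname(model_derivatives(y, p)), tolerance = 1e-12)
      }
    }
  }
})

test_that("parameter validation and regime classification work", {
  expect_error(rescue_params(rho = 1.2), "rho")
  expect_error(rescue_params(K = 0), "carrying capacity")
  expect_error(rescue_params(dt = 0), "dt")
  expect_error(rescue_params(r_A = -1), "growth rates")
  expect_equal(classify_regime(rescue_params(delta = 0.5)),
               "trivially_safe")
  expect_equal(classify_regime(rescue_params(r_M = 1.05, delta = 1.1)),
               "deterministic_extinction")
  expect_equal(classify_regime(rescue_params()), "rescue_relevant")
})

test_that("parameters round-trip through flat lists and reject unknown
           keys", {
  p <- rescue_params("mutualism", r_A = c(1, 1.2), mu = c(1e-4, 2e-4),
                     N_c = 25)
  p2 <- params_from_list(params_to_list(p))
  expect_equal(params_to_list(p2), params_to_list(p))
  expect_error(params_from_list(list(model_variant = "cooperation",
                                     nonsense = 1)), "unknown parameter")
})

test_that("initial states sit at the pre-stress equilibrium", {
  expect_equal(unclass(initial_state(rescue_params("cooperation"))),
               c(A1 = 1000, M1 = 0, A2 = 0, M2 = 0), ignore_attr = TRUE)
  s <- initial_state(rescue_params("mutualism", initial_fraction = 0.3))
  expect_equal(unname(s[c("A1", "A2")]), c(300, 700))
  sn <- initial_state(rescue_params("mutualism_no_competition"))
  expect_equal(unname(sn[c("A1", "A2")]), c(1000, 1000))
  tot <- state_totals(population_state(A1 = 3, M1 = 4, A2 = 5, M2 = 6))
  expect_equal(tot$N_T, 18)
  expect_equal(tot$N_T1, 7)
  expect_equal(tot$N_coop, 7)
  expect_error(population_state(A1 = -1), ">= 0")
})
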