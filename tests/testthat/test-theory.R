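test_that("decline times match closed forms to 1e-6 relative error", {
  # pure exponential decline (K -> Inf, no Allee)
  p1 <- rescue_params("cooperation", r_A = 0, r_M = 2, K = 1e12, N_c = 0,
                      rho = 0.5, delta = 1)
  expect_equal(ancestor_decline_time(p1, N_start = 1000, N_target = 100),
               log(10), tolerance = 1e-6)
  # logistic-with-death on a single branch (no Allee switch)
  p2 <- rescue_params("baseline", r_A = 1, r_M = 2, K = 1000, N_c = 0,
                      delta = 1.1)
  expect_equal(ancestor_decline_time(p2, N_target = 100),
               oracle_passage_time(1, 1.1, 1000, 1000, 100),
               tolerance = 1e-6)
  # piecewise decline across the Allee branch switch at N_c
  p3 <- rescue_params("cooperation", r_A = 1, r_M = 2, K = 1000, N_c = 200,
                      rho = 0.5, delta = 1.1)
  expected <- oracle_passage_time(1, 1.1, 1000, 1000, 200) +
    oracle_passage_time(0.5, 1.1, 1000, 200, 50)
  expect_equal(ancestor_decline_time(p3, N_target = 50), expected,
               tolerance = 1e-6)
  # degenerate and error cases
  expect_equal(ancestor_decline_time(p2, N_target = 1000), 0)
  expect_error(ancestor_decline_time(update_params(p2, delta = 0.2),
                                     N_target = 100), "no finite decline")
})

test_that("bare mutant growth time matches the exponential closed form", {
  p <- rescue_params("cooperation", r_M = 2, delta = 1.5, K = 1e12,
                     N_c = 100, rho = 0.6)
  expect_equal(mutant_growth_time(p, method = "bare"), log(100) / 0.5,
               tolerance = 1e-12)
  expect_equal(mutant_growth_time(update_params(p, N_c = 0)), 0)
  expect_error(mutant_growth_time(update_params(p, r_M = 1.2, rho = 0.9)),
               "cannot grow")
})

test_that("rescue window decomposes the decline and shrinks with N_c", {
  p <- rescue_params("cooperation", N_c = 30)
  w <- rescue_window(p)
  expect_equal(w$window, w$t_decline - w$t_grow, tolerance = 1e-9)
  expect_gt(w$window, 0)
  # window is non-increasing in the critical population size, and zero
  # once the mutant cannot reach N_c in time
  windows <- vapply(c(10, 30, 60, 100, 150, 250), function(nc)
    rescue_window(update_params(p, N_c = nc))$window, numeric(1))
  expect_true(all(diff(windows) <= 1e-8))
  expect_equal(windows[6], 0)
  # baseline window is the full ancestor extinction time
  pb <- rescue_params("baseline", N_c = 30)
  wb <- rescue_window(pb)
  expect_equal(wb$window,
               ancestor_decline_time(pb, N_target = pb$extinction_threshold),
               tolerance = 1e-9)
  expect_gt(wb$window, w$window)
})

test_that("theoretical rescue probability has the right degenerate limits
           and monotonicities", {
  p <- rescue_params("cooperation", N_c = 30)
  expect_equal(rescue_probability_theory(update_params(p, mu = 0)), 0)
  # zero window implies zero probability for every mutation rate
  for (mu in c(1e-5, 1e-3, 1e-1)) {
    expect_equal(rescue_probability_theory(
      update_params(p, N_c = 250, mu = mu)), 0)
  }
  p_nc <- vapply(c(10, 30, 60, 100), function(nc)
    rescue_probability_theory(update_params(p, N_c = nc)), numeric(1))
  expect_true(all(diff(p_nc) <= 1e-9))
  p_mu <- vapply(c(1e-5, 1e-4, 1e-3), function(m)
    rescue_probability_theory(update_params(p, mu = m)), numeric(1))
  expect_true(all(diff(p_mu) >= 0))
  p_rm <- vapply(c(1.5, 2, 2.1), function(r)
    rescue_probability_theory(update_params(p, r_M = r)), numeric(1))
  expect_true(all(diff(p_rm) >= 0))
  expect_error(rescue_probability_theory(rescue_params("cheater")),
               "cheater")
})

test_that("without competition the theory is the square of one species", {
  for (nc in c(10, 30)) {
    p1 <- rescue_params("cooperation", N_c = nc, mu = 3e-4)
    p2 <- rescue_params("mutualism_no_competition", N_c = nc, mu = 3e-4)
    expect_equal(rescue_probability_theory(p2),
                 rescue_probability_theory(p1)^2, tolerance = 1e-6)
  }
})

test_that("theory surfaces export windows and probabilities per grid row", {
  surf <- theory_surface(rescue_params("cooperation"),
                         expand.grid(N_c = c(20, 250), mu = c(0, 3e-4)))
  expect_equal(nrow(surf), 4)
  expect_named(surf, c("N_c", "mu", "t_decline", "t_grow", "window",
                       "p_theory"))
  expect_true(all(surf$p_theory[surf$mu == 0] == 0))
  expect_true(all(surf$p_theory[surf$N_c == 250] == 0))
  expect_true(all(surf$window[surf$N_c == 20] > 0))
})

test_that("smooth-response variants behave like the step model
           qualitatively", {
  ps <- rescue_params("cooperation", N_c = 30, allee_form = "smooth",
                      smooth_steepness = 8)
  w <- rescue_window(ps)
  expect_gt(w$window, 0)
  p_nc <- vapply(c(10, 30, 100, 250), function(nc)
    rescue_probability_theory(update_params(ps, N_c = nc)), numeric(1))
  expect_true(all(diff(p_nc) <= 1e-9))
  expect_equal(p_nc[4], 0)
})
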