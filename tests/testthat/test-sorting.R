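test_that("sorting error splits the plated cells by theta percent", {
  st <- apply_sorting_error(sorting_scenario("CSC", 1000, theta = 2),
                            m_gen = 50)
  expect_equal(st$csc, 980)
  expect_equal(st$nscc[1], 20)
  expect_equal(sum(st$nscc[-1]), 0)

  pure <- apply_sorting_error(sorting_scenario("NSCC", 500, theta = 0),
                              m_gen = 50)
  expect_equal(pure$csc, 0)
  expect_equal(sum(pure$nscc), 500)

  contaminated <- apply_sorting_error(sorting_scenario("NSCC", 1000, theta = 2),
                                      m_gen = 50)
  expect_equal(csc_proportion(contaminated), 0.02)

  expect_error(sorting_scenario("CSC", 1000, theta = 150), "\\[0, 100\\]")
})

test_that("the objective is zero on self-generated data and sums squared residuals", {
  scen <- sorting_scenario("CSC", 1000, theta = 2)
  cand <- list(k_c = 0.9, k_n = 0.5, e = 0.7)
  fixed <- list(k_t = 0, m_gen = 50L, d = 1)
  times <- seq(2, 20, 3)
  params <- cscdyn:::candidate_params(cand$k_c, cand$k_n, cand$e, fixed)
  sim <- cscdyn:::proportion_on_grid(params,
                                     apply_sorting_error(scen, 50L), times)
  self_data <- data.frame(time_days = times, csc_proportion = sim)
  expect_lt(fit_objective(cand, self_data, scen, fixed), 1e-12)

  zero_data <- data.frame(time_days = times, csc_proportion = 0)
  expect_equal(fit_objective(cand, zero_data, scen, fixed), sum(sim^2),
               tolerance = 1e-10)
})

test_that("early proportion growth separates transition from hierarchy models", {
  # with k_t = 0 and small R, dR/dt ~ R (K_C e - K_N)(1 - R): bounded by
  # |K_C e - K_N| per unit R; with k_t > 0, dR/dt ~ K_T regardless of R
  kp0 <- kinetic_params(k_t = 0)
  kp <- table1_params()
  gap0 <- kp0$k_c * effective_e(kp0$probs) - kp0$k_n
  for (R in c(0.005, 0.02, 0.05)) {
    slope0 <- reduced_proportion_rate(R, kp0)
    # leading order: dR/dt = R (K_C e - K_N) + O(R^2)
    expect_equal(slope0, R * gap0, tolerance = 2 * R)
    # per-capita growth of R is bounded near the |K_C e - K_N| gap
    expect_lt(abs(slope0) / R, abs(gap0) + R * abs(kp0$k_n - kp0$k_c) + 1e-9)
    expect_lt(abs(reduced_proportion_rate(R, kp) - kp$k_t), 0.05)
  }
})

test_that("annealing converges on a one-dimensional objective", {
  # freeze k_n and e via degenerate bounds: the objective becomes a smooth
  # 1-D function of k_c with a unique minimum at the generating value
  fixed <- list(k_t = 0, m_gen = 50L, d = 1)
  scen <- sorting_scenario("CSC", 1000, theta = 2)
  params <- cscdyn:::candidate_params(0.9, 0.45, 0.75, fixed)
  times <- seq(1, 29, 2)
  sim <- cscdyn:::proportion_on_grid(params,
                                     apply_sorting_error(scen, 50L), times)
  data <- data.frame(time_days = times, csc_proportion = sim)
  sch <- anneal_schedule(n_proposals = 600, sigma = 0.01,
                         bounds = list(k_c = c(1e-6, 3),
                                       k_n = c(0.45, 0.45),
                                       e = c(0.75, 0.75)))
  fits <- simulated_annealing_fit(data, scen, sch, fixed, n_fits = 2,
                                  seed = 7)
  best <- fits[which.min(fits$objective), ]
  expect_lt(best$objective, 1e-5)
  expect_equal(best$k_c, 0.9, tolerance = 0.01)
})

test_that("annealing recovers the identifiable rate combinations", {
  # with k_t = 0, proportion data constrain K_C e - K_N (equilibrium) and
  # K_C - K_N (relaxation speed); the third direction is a near-flat ridge
  truth <- list(k_c = 0.9, k_n = 0.45, e = 0.75)
  fixed <- list(k_t = 0, m_gen = 50L, d = 1)
  scen <- sorting_scenario("CSC", 1000, theta = 2)
  params <- cscdyn:::candidate_params(truth$k_c, truth$k_n, truth$e, fixed)
  times <- seq(1, 29, 1)
  sim <- cscdyn:::proportion_on_grid(params,
                                     apply_sorting_error(scen, 50L), times)
  data <- data.frame(time_days = times, csc_proportion = sim)
  sch <- anneal_schedule(n_proposals = 1500, sigma = 0.01)
  fits <- simulated_annealing_fit(data, scen, sch, fixed, n_fits = 3,
                                  seed = 42)
  best <- fits[which.min(fits$objective), ]
  expect_true(best$accepted)
  expect_lt(best$objective, 2e-3)
  expect_equal(best$k_c * best$e - best$k_n,
               truth$k_c * truth$e - truth$k_n, tolerance = 0.15)
  expect_equal(best$k_c - best$k_n, truth$k_c - truth$k_n, tolerance = 0.15)
})

test_that("annealing is deterministic under a fixed seed and threshold-aware", {
  scen <- sorting_scenario("CSC", 200, theta = 2)
  data <- data.frame(time_days = c(2, 5, 9), csc_proportion = c(0.9, 0.8, 0.7))
  sch <- anneal_schedule(n_proposals = 50, sigma = 1)  # huge threshold
  f1 <- simulated_annealing_fit(data, scen, sch, n_fits = 2, seed = 7)
  f2 <- simulated_annealing_fit(data, scen, sch, n_fits = 2, seed = 7)
  expect_identical(f1, f2)
  expect_true(all(f1$accepted))  # threshold effectively infinite
})

test_that("cross-evaluation flags hierarchy-only fits that fail the NSCC culture", {
  scen_csc <- sorting_scenario("CSC", 1000, theta = 2)
  scen_nscc <- sorting_scenario("NSCC", 1000, theta = 2)
  truth <- table1_params()
  times <- seq(2, 26, 2)
  csc_tc <- generate_time_course(truth, scen_csc, times, 0.02, seed = 101)
  nscc_tc <- generate_time_course(truth, scen_nscc, times, 0.02, seed = 102)
  sch <- anneal_schedule(n_proposals = 400, sigma = 0.03)
  fits <- simulated_annealing_fit(csc_tc$data, scen_csc, sch, n_fits = 6,
                                  seed = 4)
  expect_gte(sum(fits$accepted), 1)
  ce <- cross_evaluate(fits, nscc_tc$data, scen_nscc)
  expect_equal(ce$verdict, "hierarchy-insufficient")
  expect_true(all(ce$objectives > ce$threshold))

  # fits evaluated on their own training data stay below the threshold
  ce_self <- cross_evaluate(fits, csc_tc$data, scen_csc)
  expect_equal(ce_self$verdict, "hierarchy-consistent")
})

test_that("a short NSCC lifespan lets the hierarchy model equilibrate fast", {
  # the residual failure mode is the time to equilibrium, which shrinks as
  # M drops toward ~5: compare times to reach 90% of equilibrium
  t_to_eq <- function(m) {
    fixed <- list(k_t = 0, m_gen = as.integer(m), d = 1)
    params <- cscdyn:::candidate_params(k_c = 1.1, k_n = 0.5, e = 0.75, fixed)
    init <- apply_sorting_error(sorting_scenario("NSCC", 1000, 2), m)
    times <- seq(0.5, 40, 0.5)
    prop <- cscdyn:::proportion_on_grid(params, init, times)
    R_end <- prop[length(prop)]
    times[which(prop >= 0.9 * R_end)[1]]
  }
  expect_lt(t_to_eq(5), t_to_eq(50))
})
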