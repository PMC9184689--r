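test_that("the no-screening base case reproduces the published ledger", {
  traj <- run_no_screening(base_params())
  expect_equal(round(traj$per_patient_cost), 50936)
  expect_equal(round(traj$total_discounted_cost / 1e6, 1), 764.0)
  expect_equal(floor(traj$survivors_end + 0.5), 9582)
  expect_equal(floor(traj$misdiagnosed_end + 0.5), 680)
  expect_equal(floor(traj$correct_end + 0.5), 8901)
})

test_that("a homogeneous cohort with no dynamics costs T times the unit cost", {
  p <- bd_params(ubp_prevalence = 0, attrition = 0, discount = 0,
                 c_mdd = 1000, c_rbp = 1000, c_ubp = 1000, horizon = 5)
  traj <- run_no_screening(p)
  expect_equal(traj$per_patient_cost, 5 * 1000, tolerance = 1e-12)
})

test_that("without correction the misdiagnosed decay only by attrition", {
  p <- bd_params(annual_correction = 0)
  traj <- run_no_screening(p)
  expect_equal(traj$misdiagnosed_end, 15000 * 0.16 * (1 - 0.106)^4,
               tolerance = 1e-9) # ~1533
})

test_that("the iterative engine equals the closed-form cost on random draws", {
  set.seed(33)
  for (i in 1:1000) {
    params <- draw_params()
    engine <- run_no_screening(params)$per_patient_cost
    analytic <- closed_form_cost(params)
    expect_equal(engine, analytic, tolerance = 1e-9)
  }
})

test_that("yearly ledgers conserve persons and satisfy the discount identity", {
  set.seed(44)
  for (i in 1:50) {
    params <- draw_params()
    expect_year_invariants(run_no_screening(params))
    expect_year_invariants(run_screening(params, runif(1), runif(1)))
  }
})

test_that("a perfect screen with full referral leaves no misdiagnoses", {
  p <- bd_params(referral_prob = 1)
  traj <- run_screening(p, sens = 1, spec = 1)
  expect_equal(traj$misdiagnosed_end, 0, tolerance = 1e-9)
})

test_that("an inert free screen reproduces the no-screening trajectory exactly", {
  p <- bd_params(c_screen = 0)
  screened <- run_screening(p, sens = 0, spec = 1)
  plain <- run_no_screening(p)
  expect_equal(tidy(screened), tidy(plain), tolerance = 1e-12)
  expect_equal(screened$total_discounted_cost, plain$total_discounted_cost,
               tolerance = 1e-12)
})

test_that("no-screening cost is monotone in prevalence, UBP cost and correction", {
  base <- base_params()
  cost_at <- function(...) run_no_screening(bd_params_update(base, ...))$per_patient_cost
  p_grid <- vapply(c(0.05, 0.1, 0.16, 0.25, 0.35), function(p)
    cost_at(ubp_prevalence = p), numeric(1))
  expect_true(all(diff(p_grid) > 0))
  ubp_grid <- vapply(c(18000, 23696, 30000, 40000), function(cu)
    cost_at(c_ubp = cu), numeric(1))
  expect_true(all(diff(ubp_grid) > 0))
  q_grid <- vapply(c(0.05, 0.1, 0.15, 0.25), function(q)
    cost_at(annual_correction = q), numeric(1))
  expect_true(all(diff(q_grid) < 0))
})

test_that("free perfect-specificity screening never costs more than no screening", {
  set.seed(55)
  for (i in 1:50) {
    params <- draw_params()
    params <- bd_params_update(params, c_screen = 0, c_eval = 0,
                               psych_accuracy = 1)
    sens <- runif(1, 0.01, 1)
    expect_lte(run_screening(params, sens, spec = 1)$total_discounted_cost,
               run_no_screening(params)$total_discounted_cost + 1e-6)
  }
})

test_that("the microsimulation is seed-deterministic", {
  p <- base_params()
  a <- simulate_microcohort(p, n_patients = 2000, seed = 7)
  b <- simulate_microcohort(p, n_patients = 2000, seed = 7)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$per_patient_cost, b$per_patient_cost)
  c <- simulate_microcohort(p, n_patients = 2000, seed = 8)
  expect_false(identical(a$per_patient_cost, c$per_patient_cost))
})

test_that("the microsimulation agrees with the deterministic engine within 3 SE", {
  p <- base_params()
  n <- 200000

  det <- run_no_screening(p)
  sim <- simulate_microcohort(p, n_patients = n, seed = 101)
  expect_lt(abs(sim$per_patient_cost - det$per_patient_cost),
            3 * sim$per_patient_cost_se)
  frac_det <- det$misdiagnosed_end / det$n0
  se_frac <- sqrt(frac_det * (1 - frac_det) / n)
  expect_lt(abs(sim$misdiagnosed_end / n - frac_det), 3 * se_frac)

  det_s <- run_screening(p, 0.87, 0.81)
  sim_s <- simulate_microcohort(p, 0.87, 0.81, n_patients = n, seed = 102)
  expect_lt(abs(sim_s$per_patient_cost - det_s$per_patient_cost),
            3 * sim_s$per_patient_cost_se)
  frac_det_s <- det_s$misdiagnosed_end / det_s$n0
  se_frac_s <- sqrt(frac_det_s * (1 - frac_det_s) / n)
  expect_lt(abs(sim_s$misdiagnosed_end / n - frac_det_s), 3 * se_frac_s)
})

test_that("with no dynamics the simulated misdiagnoses match the expectation", {
  p <- bd_params(annual_correction = 0, attrition = 0)
  n <- 50000
  sim <- simulate_microcohort(p, n_patients = n, seed = 9)
  expected <- n * p$epi$ubp_prevalence
  se <- sqrt(n * 0.16 * 0.84)
  expect_lt(abs(sim$misdiagnosed_end - expected), 3 * se)
  expect_equal(sim$survivors_end, n)
})
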