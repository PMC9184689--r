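test_that("a singleton profile is both optima of its own sweep", {
  prof <- bd_profile(0.5, 0.8, 0.85, name = "single")
  sw <- sweep_cutoffs(base_params(), prof)
  expect_equal(nrow(sw), 1)
  expect_equal(attr(sw, "best_cost_cutoff"), 0.5)
  expect_equal(attr(sw, "best_accuracy_cutoff"), 0.5)
})

test_that("sweep optima equal exhaustive per-point re-evaluation", {
  params <- base_params()
  prof <- toy_profile()
  sw <- sweep_cutoffs(params, prof)

  brute <- purrr::pmap_dfr(
    list(prof$cutoff, prof$sensitivity, prof$specificity),
    function(cutoff, sens, spec) {
      traj <- run_screening(params, sens, spec)
      tibble::tibble(cutoff = cutoff,
                     per_patient_cost = traj$per_patient_cost,
                     misdiagnosed_end = traj$misdiagnosed_end)
    }
  )
  expect_equal(sw$per_patient_cost, brute$per_patient_cost, tolerance = 1e-12)
  expect_equal(sw$misdiagnosed_end, brute$misdiagnosed_end, tolerance = 1e-12)
  expect_equal(attr(sw, "best_cost_cutoff"),
               brute$cutoff[[which.min(brute$per_patient_cost)]])
  expect_equal(attr(sw, "best_accuracy_cutoff"),
               brute$cutoff[[which.min(brute$misdiagnosed_end)]])
  expect_equal(sw$cutoff, prof$cutoff)
})

test_that("screening a synthetic high-AUC test beats no screening on accuracy", {
  pop <- simulate_scores(10000, 0.16, 0.92, seed = 1)
  prof <- operating_points(pop)
  sw <- sweep_cutoffs(base_params(), prof)
  best <- min(sw$misdiagnosed_end)
  no_screen <- run_no_screening(base_params())
  expect_lt(best, no_screen$misdiagnosed_end)
})

test_that("an inert free screen yields an all-zero comparison", {
  p <- bd_params(c_screen = 0)
  prof <- bd_profile(0.5, 0, 1, name = "inert")
  cmp <- compare_scenarios(p, prof, cutoff = 0.5)
  expect_equal(cmp$savings_total, 0, tolerance = 1e-9)
  expect_equal(cmp$savings_per_patient, 0, tolerance = 1e-12)
  expect_equal(cmp$additional_correct, 0, tolerance = 1e-9)
  expect_equal(as.numeric(cmp$cost_by_state_delta), c(0, 0, 0), tolerance = 1e-12)
})

test_that("state cost shares add up to the per-patient cost net of one-time fees", {
  traj <- run_no_screening(base_params())
  expect_equal(sum(traj$cost_by_state), traj$per_patient_cost, tolerance = 1e-9)
  scr <- run_screening(base_params(), 0.87, 0.81)
  expect_equal(sum(scr$cost_by_state),
               scr$per_patient_cost - scr$one_time_cost / scr$n0,
               tolerance = 1e-9)
})

test_that("base-case screening at the accuracy-optimal point saves about $1400", {
  cmp <- compare_scenarios(base_params(), sens = 0.87, spec = 0.81)
  expect_equal(cmp$savings_per_patient, 1408, tolerance = 1e-3)
  expect_equal(cmp$additional_correct, 422, tolerance = 5e-3)
})

test_that("per-patient savings increase with misdiagnosis prevalence", {
  savings_at <- function(p) {
    params <- bd_params(ubp_prevalence = p)
    compare_scenarios(params, sens = 0.76, spec = 0.87)$savings_per_patient
  }
  s <- vapply(c(0.11, 0.16, 0.21), savings_at, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("unknown cutoffs are a lookup error", {
  expect_error(compare_scenarios(base_params(), toy_profile(), cutoff = 0.33),
               class = "bdscreen_lookup_error")
})

test_that("identical profiles give identical comparison rows", {
  prof <- toy_profile()
  tab <- compare_tests(base_params(), list(prof, prof))
  half <- nrow(tab) / 2
  expect_equal(tab[seq_len(half), -1], tab[half + seq_len(half), -1])
})

test_that("test comparison rows are consistent with the analytic predictive values", {
  prof <- bd_profile(0.56, 0.92, 0.75, name = "mdq-like")
  tab <- compare_tests(base_params(), prof)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$optimisation, "cost & accuracy")
  pv <- ppv_npv(0.92, 0.75, 0.16)
  expect_equal(tab$ppv, pv$ppv, tolerance = 1e-12)
  expect_equal(tab$npv, pv$npv, tolerance = 1e-12)
})

test_that("a higher-AUC test achieves no more misdiagnoses at its accuracy optimum", {
  params <- base_params()
  strong <- operating_points(simulate_scores(10000, 0.16, 0.92, seed = 1),
                             name = "strong")
  weak <- operating_points(simulate_scores(10000, 0.16, 0.80, seed = 1),
                           name = "weak")
  tab <- compare_tests(params, list(strong, weak))
  best <- tab |>
    dplyr::filter(.data$optimisation != "cost") |>
    dplyr::group_by(.data$tool) |>
    dplyr::summarise(m = min(.data$misdiagnosed_end))
  expect_lte(best$m[best$tool == "strong"], best$m[best$tool == "weak"])
})
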