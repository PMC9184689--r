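test_that("binormal separation matches the normal-quantile closed form", {
  expect_equal(binormal_separation(0.5), 0)
  # frozen from sqrt(2) * qnorm(0.92)
  expect_equal(binormal_separation(0.92), 1.9870713, tolerance = 1e-6)
  for (auc in c(0.5, 0.6, 0.75, 0.92, 0.99)) {
    expect_equal(binormal_auc(binormal_separation(auc)), auc, tolerance = 1e-12)
  }
  expect_error(binormal_separation(0.4), "auc")
  expect_error(binormal_separation(1), "auc")
})

test_that("simulated score populations are seed-deterministic", {
  a <- simulate_scores(500, 0.16, 0.92, seed = 42)
  b <- simulate_scores(500, 0.16, 0.92, seed = 42)
  expect_identical(a$score, b$score)
  expect_identical(a$label, b$label)
  c <- simulate_scores(500, 0.16, 0.92, seed = 43)
  expect_false(identical(a$score, c$score))
})

test_that("simulated populations hit the target AUC and prevalence", {
  pop <- simulate_scores(10000, 0.16, 0.92, seed = 1)
  expect_equal(empirical_auc(pop$score, pop$label), 0.92, tolerance = 0.02)
  expect_equal(mean(pop$label == "case"), 0.16, tolerance = 0.02)
  flat <- simulate_scores(10000, 0.3, 0.5, seed = 2)
  expect_equal(empirical_auc(flat$score, flat$label), 0.5, tolerance = 0.02)
})

test_that("rank-sum AUC agrees with pROC on a small population", {
  skip_if_not_installed("pROC")
  pop <- simulate_scores(300, 0.3, 0.85, seed = 9)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = pop$label, predictor = pop$score,
    levels = c("control", "case"), direction = "<", quiet = TRUE
  )))
  expect_equal(empirical_auc(pop$score, pop$label), ref, tolerance = 1e-12)
})

test_that("operating points count score >= cutoff as positive, ties positive", {
  pop <- tibble::tibble(
    label = c("case", "case", "case", "control", "control", "control"),
    score = c(2.0, 1.0, -1.0, 0.5, -0.5, -1.5)
  )
  prof <- operating_points(pop, cutoffs = 0.0)
  expect_equal(prof$sensitivity, 2 / 3)
  expect_equal(prof$specificity, 2 / 3)

  below <- operating_points(pop, cutoffs = -10)
  expect_equal(below$sensitivity, 1)
  expect_equal(below$specificity, 0)
  above <- operating_points(pop, cutoffs = 10)
  expect_equal(above$sensitivity, 0)
  expect_equal(above$specificity, 1)

  tied <- operating_points(pop, cutoffs = 1.0) # case at exactly 1.0 is positive
  expect_equal(tied$sensitivity, 2 / 3)

  expect_error(operating_points(pop, cutoffs = c(0.5, 0.2)), "cutoffs")
  expect_error(operating_points(pop, cutoffs = numeric()), "cutoffs")
})

test_that("generated profiles satisfy the monotonicity invariants", {
  for (seed in 1:5) {
    pop <- simulate_scores(2000, 0.16, 0.92, seed = seed)
    prof <- operating_points(pop)
    expect_false(is.unsorted(prof$cutoff, strictly = TRUE))
    expect_true(all(diff(prof$sensitivity) <= 0))
    expect_true(all(diff(prof$specificity) >= 0))
    expect_true(all(prof$sensitivity >= 0 & prof$sensitivity <= 1))
    expect_true(all(prof$specificity >= 0 & prof$specificity <= 1))
  }
})

test_that("bootstrap intervals bracket the point estimate and are reproducible", {
  pop <- simulate_scores(800, 0.2, 0.9, seed = 3)
  prof <- operating_points(pop, cutoffs = seq(0.1, 0.9, 0.1), n_boot = 200)
  expect_true(all(prof$sens_lo <= prof$sensitivity + 1e-12))
  expect_true(all(prof$sens_hi >= prof$sensitivity - 1e-12))
  expect_true(all(prof$spec_lo <= prof$specificity + 1e-12))
  expect_true(all(prof$spec_hi >= prof$specificity - 1e-12))
  again <- operating_points(pop, cutoffs = seq(0.1, 0.9, 0.1), n_boot = 200)
  expect_identical(as.data.frame(prof), as.data.frame(again))
})

test_that("bootstrap CI coverage of the true binormal sensitivity is near nominal", {
  mu <- binormal_separation(0.9)
  prevalence <- 0.25
  cutoff <- 0.5
  # scores are calibrated posteriors, so invert the calibration to find the
  # latent threshold, then take the case-tail probability
  z_star <- (qlogis(cutoff) - qlogis(prevalence) + mu^2 / 2) / mu
  true_sens <- 1 - pnorm(z_star - mu)
  covered <- vapply(1:200, function(seed) {
    pop <- simulate_scores(400, prevalence, 0.9, seed = seed)
    prof <- operating_points(pop, cutoffs = cutoff, n_boot = 150)
    prof$sens_lo <= true_sens && true_sens <= prof$sens_hi
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("profiles round-trip through CSV", {
  pop <- simulate_scores(500, 0.2, 0.9, seed = 5)
  prof <- operating_points(pop, cutoffs = seq(0.2, 0.8, 0.2), n_boot = 50,
                           name = "delta-like")
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, path)
  back <- read_profile(path, name = "delta-like")
  expect_equal(as.data.frame(back), as.data.frame(prof))
  expect_identical(attr(back, "profile_name"), "delta-like")
})

test_that("degenerate populations and arguments are rejected", {
  expect_error(simulate_scores(5, 0.2, 0.9, seed = 1), "n")
  expect_error(simulate_scores(100, 0, 0.9, seed = 1), "prevalence")
  expect_error(simulate_scores(100, 1, 0.9, seed = 1), "prevalence")
  expect_error(bd_profile(c(0.2, 0.5), c(0.5, 0.9), c(0.5, 0.9)), "sensitivity")
  expect_error(bd_profile(c(0.5, 0.2), c(0.9, 0.5), c(0.5, 0.9)), "cutoff")
})
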