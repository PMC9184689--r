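# Shared fixtures: the base-case parameter set and random-but-valid parameter
# draws for property-style tests.

base_params <- function() bd_params()

# A small hand-made three-point profile used for brute-force oracles.
toy_profile <- function() {
  bd_profile(
    cutoff = c(0.2, 0.5, 0.8),
    sensitivity = c(0.95, 0.80, 0.40),
    specificity = c(0.50, 0.85, 0.99),
    name = "toy"
  )
}

# Uniform draws over a wide valid region. Costs are ordered
# c_ubp > c_rbp > c_mdd so monotonicity properties are well-posed.
draw_params <- function() {
  c_mdd <- runif(1, 2000, 15000)
  c_rbp <- c_mdd + runif(1, 500, 10000)
  c_ubp <- c_rbp + runif(1, 500, 10000)
  bd_params(
    plan_size = runif(1, 1e5, 2e6),
    mde_incidence = runif(1, 0.01, 0.08),
    help_seeking = runif(1, 0.2, 0.9),
    ubp_prevalence = runif(1, 0.02, 0.35),
    annual_correction = runif(1, 0.02, 0.35),
    attrition = runif(1, 0, 0.3),
    referral_prob = runif(1, 0, 1),
    psych_accuracy = runif(1, 0.5, 1),
    horizon = sample(1:8, 1),
    c_mdd = c_mdd, c_rbp = c_rbp, c_ubp = c_ubp,
    c_screen = runif(1, 0, 50),
    c_eval = runif(1, 0, 500),
    discount = runif(1, 0, 0.08)
  )
}

params_unclass <- function(p) list(epi = p$epi, costs = p$costs)

expect_year_invariants <- function(traj) {
  yrs <- tidy(traj)
  n0 <- traj$n0
  a <- traj$params$epi$attrition
  expect_equal(yrs$mdd + yrs$rbp + yrs$ubp + yrs$mdd_as_bd, yrs$n_alive,
               tolerance = 1e-9)
  expect_equal(yrs$n_alive, n0 * (1 - a)^(yrs$year - 1), tolerance = 1e-9)
  expect_equal(yrs$discounted_cost, yrs$undiscounted_cost * yrs$discount_factor,
               tolerance = 1e-12)
  expect_equal(traj$total_discounted_cost,
               traj$one_time_cost + sum(yrs$discounted_cost), tolerance = 1e-9)
}
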