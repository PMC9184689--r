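# The deterministic cohort engine. Event order within a model year:
#   1. diagnosis correction at year start (fraction q of UBP -> RBP, and of
#      MDD-as-BD -> MDD),
#   2. cost accrual for the post-correction states,
#   3. discounting at (1+r)^-(t-1) (year 1 undiscounted),
#   4. attrition at the year boundary, applied T-1 times over T years,
#      uniformly across states (disenrolled patients stop accruing cost).
# This ordering jointly yields survivors N0*(1-a)^(T-1), year-T misdiagnoses
# N0*p*(1-q)^T*(1-a)^(T-1), and the discounted ledger of the base case.

propagate_cohort <- function(params, init, one_time_cost, scenario) {
  e <- params$epi
  co <- params$costs
  q <- e$annual_correction
  a <- e$attrition
  r <- co$discount
  horizon <- e$horizon
  n0 <- sum(init)

  states <- init # named: mdd, rbp, ubp, mdd_as_bd
  rows <- vector("list", horizon)
  cost_state <- c(mdd = 0, rbp = 0, misdiagnosis = 0)
  for (t in seq_len(horizon)) {
    corr_ubp <- q * states[["ubp"]]
    corr_mab <- q * states[["mdd_as_bd"]]
    states[["ubp"]] <- states[["ubp"]] - corr_ubp
    states[["rbp"]] <- states[["rbp"]] + corr_ubp
    states[["mdd_as_bd"]] <- states[["mdd_as_bd"]] - corr_mab
    states[["mdd"]] <- states[["mdd"]] + corr_mab

    undisc <- states[["mdd"]] * co$c_mdd + states[["rbp"]] * co$c_rbp +
      states[["ubp"]] * co$c_ubp + states[["mdd_as_bd"]] * co$c_mdd_as_bd
    df <- (1 + r)^-(t - 1)
    cost_state <- cost_state + df * c(
      mdd = states[["mdd"]] * co$c_mdd,
      rbp = states[["rbp"]] * co$c_rbp,
      misdiagnosis = states[["ubp"]] * co$c_ubp +
        states[["mdd_as_bd"]] * co$c_mdd_as_bd
    )
    rows[[t]] <- tibble::tibble(
      year = t,
      n_alive = sum(states),
      mdd = states[["mdd"]],
      rbp = states[["rbp"]],
      ubp = states[["ubp"]],
      mdd_as_bd = states[["mdd_as_bd"]],
      undiscounted_cost = undisc,
      discount_factor = df,
      discounted_cost = undisc * df
    )
    if (t < horizon) states <- states * (1 - a)
  }
  years <- dplyr::bind_rows(rows)

  total <- one_time_cost + sum(years$discounted_cost)
  misdx_end <- states[["ubp"]] + states[["mdd_as_bd"]]
  structure(
    list(
      scenario = scenario,
      n0 = n0,
      years = years,
      one_time_cost = one_time_cost,
      total_discounted_cost = total,
      per_patient_cost = total / n0,
      survivors_end = sum(states),
      correct_end = sum(states) - misdx_end,
      misdiagnosed_end = misdx_end,
      cost_by_state = cost_state / n0,
      params = params
    ),
    class = "bd_trajectory"
  )
}

#' Five-year cohort trajectory without screening
#'
#' Starts the incident MDD cohort in its natural states (a fraction
#' `ubp_prevalence` unrecognised bipolar, the rest correctly diagnosed MDD)
#' and propagates it over the horizon with annual diagnosis correction,
#' attrition and discounting.
#'
#' @param params A [bd_params()] object.
#' @return A `bd_trajectory`: per-year ledger (see [tidy()]) plus
#'   end-of-horizon summaries (see [glance()]).
#' @examples
#' traj <- run_no_screening(bd_params())
#' glance(traj)
#' @export
run_no_screening <- function(params) {
  stopifnot(inherits(params, "bd_params"))
  n0 <- target_cohort(params)
  p <- params$epi$ubp_prevalence
  init <- c(mdd = n0 * (1 - p), rbp = 0, ubp = n0 * p, mdd_as_bd = 0)
  propagate_cohort(params, init, one_time_cost = 0, scenario = "no screening")
}

#' Five-year cohort trajectory with one-time screening
#'
#' Applies [apply_cascade()] at time zero to set the initial diagnostic
#' states and one-time costs, then propagates with the same yearly dynamics
#' as [run_no_screening()]; the annual correction applies symmetrically to
#' both misdiagnosed states (UBP to RBP, MDD-as-BD back to MDD).
#'
#' @param params A [bd_params()] object.
#' @param sens,spec Operating point of the screen.
#' @return A `bd_trajectory`.
#' @examples
#' glance(run_screening(bd_params(), 0.87, 0.81))
#' @export
run_screening <- function(params, sens, spec) {
  outcome <- apply_cascade(params, sens, spec)
  init <- c(mdd = outcome$mdd0, rbp = outcome$rbp0,
            ubp = outcome$ubp0, mdd_as_bd = outcome$mdd_as_bd0)
  traj <- propagate_cohort(params, init, one_time_cost = outcome$one_time_cost,
                           scenario = sprintf("screening (sens=%.2f, spec=%.2f)", sens, spec))
  traj$screen <- outcome
  traj
}

#' Analytic per-patient cost of the no-screening scenario
#'
#' Closed form of the discounted ledger: with survival-and-discount factor
#' `rho = (1 - a) / (1 + r)`, the cost per initial patient is
#' `sum_t rho^(t-1) * ((1-p) c_mdd + p (1-q)^t c_ubp + p (1-(1-q)^t) c_rbp)`.
#' Used as an independent oracle for the iterative engine.
#'
#' @param params A [bd_params()] object.
#' @return USD per patient (unrounded).
#' @export
closed_form_cost <- function(params) {
  stopifnot(inherits(params, "bd_params"))
  e <- params$epi
  co <- params$costs
  p <- e$ubp_prevalence
  q <- e$annual_correction
  rho <- (1 - e$attrition) / (1 + co$discount)
  t <- seq_len(e$horizon)
  sum(rho^(t - 1) * ((1 - p) * co$c_mdd +
                       p * (1 - q)^t * co$c_ubp +
                       p * (1 - (1 - q)^t) * co$c_rbp))
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("<bd_trajectory: %s>\n", x$scenario))
  cat(sprintf("  cohort %s, horizon %d years\n",
              format(round_half_up(x$n0), big.mark = ","), nrow(x$years)))
  cat(sprintf("  total discounted cost  $%s (one-time $%s)\n",
              format(round_half_up(x$total_discounted_cost), big.mark = ","),
              format(round_half_up(x$one_time_cost), big.mark = ",")))
  cat(sprintf("  per-patient cost       $%s\n",
              format(round_half_up(x$per_patient_cost), big.mark = ",")))
  cat(sprintf("  survivors at year %d    %s (%s correct, %s misdiagnosed)\n",
              nrow(x$years),
              format(round_half_up(x$survivors_end), big.mark = ","),
              format(round_half_up(x$correct_end), big.mark = ","),
              format(round_half_up(x$misdiagnosed_end), big.mark = ",")))
  invisible(x)
}

#' Individual-level microsimulation of the cohort model
#'
#' Stochastic counterpart of the deterministic engine: each patient's true
#' diagnosis, screen result, referral, psychiatrist verdict, yearly diagnosis
#' correction and disenrolment are independent coin flips. Aggregates to the
#' same trajectory shape; the deterministic engine is its exact expectation.
#'
#' @param params A [bd_params()] object.
#' @param sens,spec Operating point; both `NULL` simulates the no-screening
#'   scenario.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return A `bd_trajectory` with an extra element `per_patient_cost_se`, the
#'   Monte-Carlo standard error of the per-patient cost.
#' @examples
#' sim <- simulate_microcohort(bd_params(), n_patients = 5000, seed = 1)
#' glance(sim)
#' @export
simulate_microcohort <- function(params, sens = NULL, spec = NULL,
                                 n_patients, seed) {
  stopifnot(inherits(params, "bd_params"))
  n <- check_count(n_patients, "n_patients", min = 1)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  screening <- !is.null(sens) || !is.null(spec)
  if (screening) {
    check_prob(sens, "sens")
    check_prob(spec, "spec")
  }
  e <- params$epi
  co <- params$costs
  horizon <- e$horizon

  state_cost <- c(mdd = co$c_mdd, rbp = co$c_rbp,
                  ubp = co$c_ubp, mdd_as_bd = co$c_mdd_as_bd)

  sim <- withr::with_seed(seed, {
    is_bd <- stats::runif(n) < e$ubp_prevalence
    one_time <- 0
    if (screening) {
      positive <- ifelse(is_bd,
                         stats::runif(n) < sens,
                         stats::runif(n) < (1 - spec))
      referred <- positive & (stats::runif(n) < e$referral_prob)
      corrected <- referred & (stats::runif(n) < e$psych_accuracy)
      # positives carry a BD label unless a psychiatrist overrides it
      state <- ifelse(is_bd,
                      ifelse(positive,
                             ifelse(referred & !corrected, "ubp", "rbp"),
                             "ubp"),
                      ifelse(positive,
                             ifelse(corrected, "mdd", "mdd_as_bd"),
                             "mdd"))
      one_time <- n * co$c_screen + sum(referred) * co$c_eval
    } else {
      state <- ifelse(is_bd, "ubp", "mdd")
    }
    state <- factor(state, levels = names(state_cost))

    alive <- rep(TRUE, n)
    indiv_cost <- rep(one_time / n, n)
    rows <- vector("list", horizon)
    cost_state <- c(mdd = 0, rbp = 0, misdiagnosis = 0)
    for (t in seq_len(horizon)) {
      flip <- stats::runif(n) < e$annual_correction
      state[alive & flip & state == "ubp"] <- "rbp"
      state[alive & flip & state == "mdd_as_bd"] <- "mdd"
      df <- (1 + co$discount)^-(t - 1)
      yearly <- ifelse(alive, state_cost[as.integer(state)], 0)
      indiv_cost <- indiv_cost + df * yearly
      cost_state <- cost_state + df * c(
        mdd = sum(yearly[state == "mdd"]),
        rbp = sum(yearly[state == "rbp"]),
        misdiagnosis = sum(yearly[state %in% c("ubp", "mdd_as_bd")])
      )
      counts <- table(state[alive])
      rows[[t]] <- tibble::tibble(
        year = t,
        n_alive = sum(alive),
        mdd = as.numeric(counts[["mdd"]]),
        rbp = as.numeric(counts[["rbp"]]),
        ubp = as.numeric(counts[["ubp"]]),
        mdd_as_bd = as.numeric(counts[["mdd_as_bd"]]),
        undiscounted_cost = sum(yearly),
        discount_factor = df,
        discounted_cost = df * sum(yearly)
      )
      if (t < horizon) alive <- alive & (stats::runif(n) >= e$attrition)
    }
    list(rows = rows, indiv_cost = indiv_cost, one_time = one_time,
         state = state, alive = alive, cost_state = cost_state)
  })

  years <- dplyr::bind_rows(sim$rows)
  total <- sim$one_time + sum(years$discounted_cost)
  misdx <- sum(sim$alive & sim$state %in% c("ubp", "mdd_as_bd"))
  structure(
    list(
      scenario = if (screening) "microsimulation (screening)" else "microsimulation (no screening)",
      n0 = n,
      years = years,
      one_time_cost = sim$one_time,
      total_discounted_cost = total,
      per_patient_cost = total / n,
      per_patient_cost_se = stats::sd(sim$indiv_cost) / sqrt(n),
      survivors_end = sum(sim$alive),
      correct_end = sum(sim$alive) - misdx,
      misdiagnosed_end = misdx,
      cost_by_state = sim$cost_state / n,
      params = params
    ),
    class = "bd_trajectory"
  )
}
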