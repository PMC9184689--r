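#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-year ledger of a cohort trajectory
#'
#' @param x A `bd_trajectory`.
#' @param ... Unused.
#' @return A tibble with one row per model year: state counts (after that
#'   year's diagnosis correction), undiscounted cost, discount factor and
#'   discounted cost.
#' @method tidy bd_trajectory
#' @export
tidy.bd_trajectory <- function(x, ...) {
  x$years
}

#' End-of-horizon summary of a cohort trajectory
#'
#' @param x A `bd_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: scenario, cohort size, one-time / total / per
#'   patient discounted costs, survivors and correct vs misdiagnosed counts
#'   at the end of the horizon, and the per-patient cost attributed to each
#'   state bucket (correct MDD, recognised BD, misdiagnosis).
#' @method glance bd_trajectory
#' @export
glance.bd_trajectory <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario,
    n0 = x$n0,
    one_time_cost = x$one_time_cost,
    total_discounted_cost = x$total_discounted_cost,
    per_patient_cost = x$per_patient_cost,
    survivors_end = x$survivors_end,
    correct_end = x$correct_end,
    misdiagnosed_end = x$misdiagnosed_end,
    cost_pp_mdd = x$cost_by_state[["mdd"]],
    cost_pp_rbp = x$cost_by_state[["rbp"]],
    cost_pp_misdiagnosis = x$cost_by_state[["misdiagnosis"]]
  )
}

#' @method tidy bd_sweep
#' @export
tidy.bd_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Optima of a cutoff sweep
#'
#' @param x A `bd_sweep` from [sweep_cutoffs()].
#' @param ... Unused.
#' @return A one-row tibble with the cost-minimising and
#'   misdiagnosis-minimising cutoffs and their headline figures.
#' @method glance bd_sweep
#' @export
glance.bd_sweep <- function(x, ...) {
  best_cost <- attr(x, "best_cost_cutoff")
  best_acc <- attr(x, "best_accuracy_cutoff")
  row_cost <- x[abs(x$cutoff - best_cost) < 1e-9, ]
  row_acc <- x[abs(x$cutoff - best_acc) < 1e-9, ]
  tibble::tibble(
    profile = attr(x, "profile_name") %||% NA_character_,
    n_cutoffs = nrow(x),
    best_cost_cutoff = best_cost,
    best_cost_per_patient = row_cost$per_patient_cost,
    best_accuracy_cutoff = best_acc,
    best_accuracy_misdiagnosed = row_acc$misdiagnosed_end
  )
}

#' Summary of a scenario comparison
#'
#' @param x A `bd_comparison` from [compare_scenarios()].
#' @param ... Unused.
#' @return A one-row tibble of savings and accuracy gains of screening over
#'   no screening, with the per-patient cost shift in each state bucket.
#' @method glance bd_comparison
#' @export
glance.bd_comparison <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff %||% NA_real_,
    sensitivity = x$sens,
    specificity = x$spec,
    no_screening_pp = x$reference$per_patient_cost,
    screening_pp = x$comparator$per_patient_cost,
    savings_per_patient = x$savings_per_patient,
    savings_total = x$savings_total,
    additional_correct = x$additional_correct,
    delta_cost_pp_mdd = x$cost_by_state_delta[["mdd"]],
    delta_cost_pp_rbp = x$cost_by_state_delta[["rbp"]],
    delta_cost_pp_misdiagnosis = x$cost_by_state_delta[["misdiagnosis"]]
  )
}
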