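#' Sweep a screening test's cutoff grid
#'
#' Runs the screening scenario once per operating point of a test profile and
#' records per-patient and total discounted cost, year-end misdiagnoses and
#' correct diagnoses at each cutoff. Optimisation is exhaustive over the
#' supplied discrete grid (no interpolation); ties break toward the lower
#' cutoff.
#'
#' @param params A [bd_params()] object.
#' @param profile A [bd_profile()] cutoff table.
#' @return A `bd_sweep` tibble (one row per cutoff) with attributes
#'   `best_cost_cutoff` (minimises per-patient cost) and
#'   `best_accuracy_cutoff` (minimises year-end misdiagnoses).
#' @examples
#' prof <- bd_profile(c(0.2, 0.5, 0.8), c(0.95, 0.80, 0.40), c(0.50, 0.85, 0.99))
#' sweep_cutoffs(bd_params(), prof)
#' @export
sweep_cutoffs <- function(params, profile) {
  stopifnot(inherits(params, "bd_params"), inherits(profile, "bd_profile"))
  records <- purrr::pmap(
    list(profile$cutoff, profile$sensitivity, profile$specificity),
    function(cutoff, sens, spec) {
      traj <- run_screening(params, sens, spec)
      tibble::tibble(
        cutoff = cutoff,
        sensitivity = sens,
        specificity = spec,
        per_patient_cost = traj$per_patient_cost,
        total_cost = traj$total_discounted_cost,
        misdiagnosed_end = traj$misdiagnosed_end,
        correct_end = traj$correct_end
      )
    }
  ) |> dplyr::bind_rows()

  structure(records,
    class = c("bd_sweep", class(tibble::tibble())),
    profile_name = attr(profile, "profile_name"),
    best_cost_cutoff = records$cutoff[[which.min(records$per_patient_cost)]],
    best_accuracy_cutoff = records$cutoff[[which.min(records$misdiagnosed_end)]]
  )
}

#' Compare screening at one cutoff against no screening
#'
#' @param params A [bd_params()] object.
#' @param profile A [bd_profile()] cutoff table; the operating point is looked
#'   up at `cutoff`. Alternatively pass `sens` and `spec` directly with
#'   `profile = NULL`.
#' @param cutoff A cutoff present in `profile`.
#' @param sens,spec Operating point, used when no profile is given.
#' @return A `bd_comparison` list: the two `bd_trajectory` objects
#'   (`reference`, `comparator`), `savings_total`, `savings_per_patient`,
#'   `additional_correct`, and `cost_by_state_delta` (comparator minus
#'   reference, USD per patient).
#' @examples
#' cmp <- compare_scenarios(bd_params(), sens = 0.87, spec = 0.81)
#' glance(cmp)
#' @export
compare_scenarios <- function(params, profile = NULL, cutoff = NULL,
                              sens = NULL, spec = NULL) {
  stopifnot(inherits(params, "bd_params"))
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "bd_profile"))
    if (is.null(cutoff)) abort_field("cutoff", "is required when a profile is given")
    hit <- which(abs(profile$cutoff - cutoff) < 1e-9)
    if (length(hit) != 1L) {
      abort_field("cutoff", sprintf("%s is not a cutoff of the profile", cutoff),
                  class = "bdscreen_lookup_error")
    }
    sens <- profile$sensitivity[[hit]]
    spec <- profile$specificity[[hit]]
  }
  if (is.null(sens) || is.null(spec)) {
    abort_field("sens", "and spec (or profile + cutoff) are required")
  }
  reference <- run_no_screening(params)
  comparator <- run_screening(params, sens, spec)
  structure(
    list(
      reference = reference,
      comparator = comparator,
      cutoff = cutoff,
      sens = sens,
      spec = spec,
      savings_total = reference$total_discounted_cost - comparator$total_discounted_cost,
      savings_per_patient = reference$per_patient_cost - comparator$per_patient_cost,
      additional_correct = comparator$correct_end - reference$correct_end,
      cost_by_state_delta = comparator$cost_by_state - reference$cost_by_state
    ),
    class = "bd_comparison"
  )
}

#' @export
print.bd_comparison <- function(x, ...) {
  cat(sprintf("<bd_comparison: %s vs %s>\n", x$comparator$scenario, x$reference$scenario))
  cat(sprintf("  savings  $%s total, $%s per patient\n",
              format(round_half_up(x$savings_total), big.mark = ","),
              format(round_half_up(x$savings_per_patient), big.mark = ",")))
  cat(sprintf("  %s additional correct diagnoses at year %d\n",
              format(round_half_up(x$additional_correct), big.mark = ","),
              x$reference$params$epi$horizon))
  invisible(x)
}

#' Compare screening tests at their optimal cutoffs
#'
#' For each profile, sweeps the cutoff grid and reports one row per
#' optimisation criterion (lowest cost, fewest misdiagnoses; merged when the
#' same cutoff wins both) with the operating characteristics, predictive
#' values, per-patient cost, year-end misdiagnoses and savings versus no
#' screening.
#'
#' @param params A [bd_params()] object.
#' @param profiles A list of [bd_profile()] objects (or a single profile).
#' @return A tibble with columns `tool`, `cutoff`, `optimisation`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `per_patient_cost`,
#'   `misdiagnosed_end`, `savings_per_patient`.
#' @export
compare_tests <- function(params, profiles) {
  stopifnot(inherits(params, "bd_params"))
  if (inherits(profiles, "bd_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) abort_field("profiles", "must contain at least one profile")
  p <- params$epi$ubp_prevalence
  no_screen <- run_no_screening(params)

  purrr::map(profiles, function(profile) {
    sw <- sweep_cutoffs(params, profile)
    optima <- c(cost = attr(sw, "best_cost_cutoff"),
                accuracy = attr(sw, "best_accuracy_cutoff"))
    if (optima[["cost"]] == optima[["accuracy"]]) {
      optima <- c(`cost & accuracy` = optima[["cost"]])
    }
    purrr::imap(optima, function(cut, label) {
      row <- sw[abs(sw$cutoff - cut) < 1e-9, ]
      pv <- ppv_npv(row$sensitivity, row$specificity, p)
      tibble::tibble(
        tool = attr(profile, "profile_name"),
        cutoff = cut,
        optimisation = label,
        sensitivity = row$sensitivity,
        specificity = row$specificity,
        ppv = pv$ppv,
        npv = pv$npv,
        per_patient_cost = row$per_patient_cost,
        misdiagnosed_end = row$misdiagnosed_end,
        savings_per_patient = no_screen$per_patient_cost - row$per_patient_cost
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
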