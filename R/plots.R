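#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cutoff sweep
#'
#' Per-patient discounted cost and year-end misdiagnoses across the cutoff
#' grid, with the cost- and accuracy-optimal cutoffs marked.
#'
#' @param object A `bd_sweep` from [sweep_cutoffs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bd_sweep
#' @export
autoplot.bd_sweep <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("cutoff", "per_patient_cost", "misdiagnosed_end") |>
    tidyr::pivot_longer(-"cutoff", names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
      per_patient_cost = "per-patient cost (USD)",
      misdiagnosed_end = "misdiagnosed at horizon (persons)"
    ))
  marks <- tibble::tibble(
    cutoff = c(attr(object, "best_cost_cutoff"), attr(object, "best_accuracy_cutoff")),
    optimum = c("lowest cost", "fewest misdiagnoses")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$cutoff, colour = .data$optimum),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "diagnostic cutoff", y = NULL, colour = NULL,
      title = sprintf("Screening performance across cutoffs (%s)",
                      attr(object, "profile_name"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a decision curve
#'
#' @param object A `bd_decision_curve` from [decision_curve()].
#' @param ... Unused.
#' @return A ggplot of model, treat-all and treat-none net benefit.
#' @method autoplot bd_decision_curve
#' @export
autoplot.bd_decision_curve <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("pt", "nb_model", "nb_all", "nb_none") |>
    tidyr::pivot_longer(-"pt", names_to = "strategy", values_to = "net_benefit") |>
    dplyr::mutate(strategy = dplyr::recode(.data$strategy,
      nb_model = "screening model", nb_all = "treat all as BD",
      nb_none = "treat none"
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pt, y = .data$net_benefit,
                                     colour = .data$strategy,
                                     linetype = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "threshold probability", y = "net benefit",
                  colour = NULL, linetype = NULL,
                  title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}

#' Plot a cohort trajectory
#'
#' Stacked state counts per model year (after each year's diagnosis
#' correction and before that year's attrition).
#'
#' @param object A `bd_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bd_trajectory
#' @export
autoplot.bd_trajectory <- function(object, ...) {
  long <- object$years |>
    dplyr::select("year", "mdd", "rbp", "ubp", "mdd_as_bd") |>
    tidyr::pivot_longer(-"year", names_to = "state", values_to = "persons") |>
    dplyr::mutate(state = factor(.data$state,
                                 levels = c("mdd", "rbp", "ubp", "mdd_as_bd"),
                                 labels = c("MDD (correct)", "RBP", "UBP",
                                            "MDD as BD")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$persons,
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "model year", y = "persons enrolled", fill = NULL,
                  title = object$scenario) +
    ggplot2::theme_minimal()
}

#' Plot the per-patient cost breakdown of a comparison
#'
#' Stacked per-patient discounted costs by state bucket (correct MDD,
#' recognised BD, misdiagnosis) for the no-screening and screening arms.
#'
#' @param object A `bd_comparison` from [compare_scenarios()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bd_comparison
#' @export
autoplot.bd_comparison <- function(object, ...) {
  breakdown <- function(traj, label) {
    tibble::tibble(
      scenario = label,
      bucket = factor(c("MDD (correct)", "RBP", "UBP / misdiagnosis"),
                      levels = c("UBP / misdiagnosis", "RBP", "MDD (correct)")),
      cost_pp = as.numeric(traj$cost_by_state[c("mdd", "rbp", "misdiagnosis")])
    )
  }
  long <- dplyr::bind_rows(
    breakdown(object$reference, "no screening"),
    breakdown(object$comparator, "screening")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$cost_pp,
                                     fill = .data$bucket)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "discounted cost per patient (USD)",
                  fill = NULL, title = "Cost distribution by diagnostic state") +
    ggplot2::theme_minimal()
}
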