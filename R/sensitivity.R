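#' One-way sensitivity analysis
#'
#' Perturbs one model assumption at a time, reruns both scenarios, and
#' reports discounted per-patient costs with and without screening plus the
#' savings. The base case is restored between rows. Overrides naming `sens`
#' or `spec` change the screening operating point instead of a model
#' parameter.
#'
#' @param params Base-case [bd_params()].
#' @param sens,spec Base-case operating point of the screen.
#' @param plan A tibble with columns `parameter` (label), `variant` (label)
#'   and `overrides` (list column of named value lists), e.g. from
#'   [default_sensitivity_plan()].
#' @return A tibble with one row per variant: `parameter`, `variant`,
#'   `no_screening_pp`, `screening_pp`, `savings_pp` (all USD per patient,
#'   unrounded).
#' @examples
#' params <- bd_params()
#' one_way_sensitivity(params, 0.76, 0.87, default_sensitivity_plan(params))
#' @export
one_way_sensitivity <- function(params, sens, spec, plan) {
  stopifnot(inherits(params, "bd_params"))
  check_prob(sens, "sens")
  check_prob(spec, "spec")
  if (!is.data.frame(plan) ||
      !all(c("parameter", "variant", "overrides") %in% names(plan))) {
    abort_field("plan", "must have columns parameter, variant, overrides")
  }
  if (nrow(plan) == 0L) {
    return(tibble::tibble(parameter = character(), variant = character(),
                          no_screening_pp = numeric(), screening_pp = numeric(),
                          savings_pp = numeric()))
  }

  purrr::pmap(plan[c("parameter", "variant", "overrides")],
    function(parameter, variant, overrides) {
      op <- overrides[names(overrides) %in% c("sens", "spec")]
      par_over <- overrides[!names(overrides) %in% c("sens", "spec")]
      v_params <- if (length(par_over)) {
        do.call(bd_params_update, c(list(params), par_over))
      } else {
        params
      }
      v_sens <- if ("sens" %in% names(op)) op$sens else sens
      v_spec <- if ("spec" %in% names(op)) op$spec else spec
      ns <- run_no_screening(v_params)$per_patient_cost
      sc <- run_screening(v_params, v_sens, v_spec)$per_patient_cost
      tibble::tibble(parameter = parameter, variant = variant,
                     no_screening_pp = ns, screening_pp = sc,
                     savings_pp = ns - sc)
    }) |> dplyr::bind_rows()
}

#' The built-in one-way sensitivity plan
#'
#' The thirteen variants of the model's published one-way analysis: low/high
#' unrecognised-bipolar prevalence (11%, 21%); low-sensitivity/high-specificity
#' and high-sensitivity/low-specificity operating points (0.58/0.97,
#' 0.92/0.75, the screen's 95% CI bounds); joint 50%/150% scaling of the RBP
#' and UBP unit costs; joint 50%/150% scaling of the MDD and UBP unit costs;
#' setting the MDD cost equal to the RBP cost ("RBP = MDD"); low/high annual
#' correction (10%, 20%); and low/high referral probability (50%, 100%).
#' Cost scalings are expressed as absolute values computed from `params`, and
#' the MDD-as-BD cost tracks the UBP cost throughout.
#'
#' @param params Base-case [bd_params()] the scalings are derived from.
#' @return A plan tibble for [one_way_sensitivity()] (13 rows).
#' @export
default_sensitivity_plan <- function(params) {
  stopifnot(inherits(params, "bd_params"))
  co <- params$costs
  variant <- function(parameter, variant, overrides) {
    tibble::tibble(parameter = parameter, variant = variant,
                   overrides = list(overrides))
  }
  dplyr::bind_rows(
    variant("ubp_prevalence", "low (11%)", list(ubp_prevalence = 0.11)),
    variant("ubp_prevalence", "high (21%)", list(ubp_prevalence = 0.21)),
    variant("operating point", "low sens, high spec (0.58, 0.97)",
            list(sens = 0.58, spec = 0.97)),
    variant("operating point", "high sens, low spec (0.92, 0.75)",
            list(sens = 0.92, spec = 0.75)),
    variant("cost of RBP relative to UBP", "high (150%)",
            list(c_rbp = 1.5 * co$c_rbp, c_ubp = 1.5 * co$c_ubp,
                 c_mdd_as_bd = 1.5 * co$c_ubp)),
    variant("cost of RBP relative to UBP", "low (50%)",
            list(c_rbp = 0.5 * co$c_rbp, c_ubp = 0.5 * co$c_ubp,
                 c_mdd_as_bd = 0.5 * co$c_ubp)),
    variant("cost of MDD relative to UBP", "high (150%)",
            list(c_mdd = 1.5 * co$c_mdd, c_ubp = 1.5 * co$c_ubp,
                 c_mdd_as_bd = 1.5 * co$c_ubp)),
    variant("cost of MDD relative to UBP", "low (50%)",
            list(c_mdd = 0.5 * co$c_mdd, c_ubp = 0.5 * co$c_ubp,
                 c_mdd_as_bd = 0.5 * co$c_ubp)),
    variant("cost of RBP relative to MDD", "RBP = MDD",
            list(c_mdd = co$c_rbp)),
    variant("annual_correction", "low (10%)", list(annual_correction = 0.10)),
    variant("annual_correction", "high (20%)", list(annual_correction = 0.20)),
    variant("referral_prob", "low (50%)", list(referral_prob = 0.50)),
    variant("referral_prob", "high (100%)", list(referral_prob = 1.00))
  )
}
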