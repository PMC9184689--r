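#' Model parameters for the screening cost model
#'
#' Bundles every epidemiological, behavioural and cost assumption of the
#' five-year decision-analysis model into one validated object. Defaults are
#' the model's base case: a health plan of one million members, a 3% one-year
#' incidence of a major depressive episode of whom half seek care (a cohort of
#' 15,000 new MDD diagnoses), 16% of whom are unrecognised bipolar-disorder
#' patients (UBP); a 15%/year chance of spontaneous diagnosis correction,
#' 10.6%/year all-cause plan disenrolment, a 75% chance that a screen-positive
#' patient sees a psychiatrist (who diagnoses with perfect accuracy), a 5-year
#' horizon, 2021 USD state costs, and 3%/year discounting.
#'
#' @param plan_size Health-plan membership (persons).
#' @param mde_incidence One-year incidence of a major depressive episode.
#' @param help_seeking Fraction of affected members who visit a physician.
#' @param ubp_prevalence Fraction of new MDD diagnoses that are unrecognised
#'   bipolar disorder.
#' @param annual_correction Yearly probability that a misdiagnosed patient
#'   switches to the correct diagnosis without screening.
#' @param attrition Yearly probability of all-cause plan disenrolment;
#'   disenrolled patients stop accruing cost.
#' @param referral_prob Probability that a screen-positive patient visits a
#'   psychiatrist.
#' @param psych_accuracy Probability that the psychiatrist assigns the true
#'   diagnosis.
#' @param horizon Follow-up horizon in whole years.
#' @param c_mdd,c_rbp,c_ubp Annual direct cost (USD) of correctly diagnosed
#'   MDD, recognised bipolar disorder (RBP), and unrecognised bipolar disorder
#'   (UBP).
#' @param c_mdd_as_bd Annual direct cost of an MDD patient mislabelled as
#'   bipolar after an unverified positive screen. Defaults to `c_ubp` (the
#'   model's stated assumption) and then tracks `c_ubp` through updates.
#' @param c_screen One-time screening cost per screened person (USD).
#' @param c_eval One-time psychiatric evaluation cost per referral (USD).
#' @param discount Annual discount rate applied to future costs (year 1 is
#'   undiscounted).
#' @param currency_year Calendar year the unit costs are expressed in.
#'
#' @return A `bd_params` object: a list with elements `epi` and `costs`.
#' @seealso [bd_params_update()], [read_bd_params()], [target_cohort()]
#' @examples
#' params <- bd_params()
#' target_cohort(params)
#' @export
bd_params <- function(plan_size = 1e6,
                      mde_incidence = 0.03,
                      help_seeking = 0.50,
                      ubp_prevalence = 0.16,
                      annual_correction = 0.15,
                      attrition = 0.106,
                      referral_prob = 0.75,
                      psych_accuracy = 1,
                      horizon = 5,
                      c_mdd = 11760,
                      c_rbp = 16092,
                      c_ubp = 23696,
                      c_mdd_as_bd = NULL,
                      c_screen = 15,
                      c_eval = 230,
                      discount = 0.03,
                      currency_year = 2021) {
  check_positive(plan_size, "plan_size")
  check_prob(mde_incidence, "mde_incidence")
  check_prob(help_seeking, "help_seeking")
  check_prob(ubp_prevalence, "ubp_prevalence")
  check_prob(annual_correction, "annual_correction")
  check_prob(attrition, "attrition")
  check_prob(referral_prob, "referral_prob")
  check_prob(psych_accuracy, "psych_accuracy")
  horizon <- check_count(horizon, "horizon", min = 1)
  check_nonneg(c_mdd, "c_mdd")
  check_nonneg(c_rbp, "c_rbp")
  check_nonneg(c_ubp, "c_ubp")
  follows <- is.null(c_mdd_as_bd)
  if (follows) c_mdd_as_bd <- c_ubp
  check_nonneg(c_mdd_as_bd, "c_mdd_as_bd")
  check_nonneg(c_screen, "c_screen")
  check_nonneg(c_eval, "c_eval")
  check_nonneg(discount, "discount")
  check_number(currency_year, "currency_year")
  if (plan_size * mde_incidence * help_seeking <= 0) {
    abort_field("plan_size", "x mde_incidence x help_seeking must give a positive cohort")
  }

  structure(
    list(
      epi = list(
        plan_size = plan_size,
        mde_incidence = mde_incidence,
        help_seeking = help_seeking,
        ubp_prevalence = ubp_prevalence,
        annual_correction = annual_correction,
        attrition = attrition,
        referral_prob = referral_prob,
        psych_accuracy = psych_accuracy,
        horizon = horizon
      ),
      costs = list(
        c_mdd = c_mdd,
        c_rbp = c_rbp,
        c_ubp = c_ubp,
        c_mdd_as_bd = c_mdd_as_bd,
        c_screen = c_screen,
        c_eval = c_eval,
        discount = discount,
        currency_year = currency_year
      )
    ),
    class = "bd_params",
    mdd_as_bd_follows_ubp = follows
  )
}

#' @export
print.bd_params <- function(x, ...) {
  e <- x$epi
  co <- x$costs
  cat("<bd_params>\n")
  cat(sprintf(
    "  cohort: %s plan x %.1f%% MDE incidence x %.0f%% help-seeking = %s new MDD diagnoses\n",
    format(e$plan_size, big.mark = ","), 100 * e$mde_incidence,
    100 * e$help_seeking, format(round_half_up(target_cohort(x)), big.mark = ",")
  ))
  cat(sprintf(
    "  epi: UBP prevalence %.0f%%, correction %.0f%%/yr, attrition %.1f%%/yr, referral %.0f%%, horizon %d yr\n",
    100 * e$ubp_prevalence, 100 * e$annual_correction, 100 * e$attrition,
    100 * e$referral_prob, e$horizon
  ))
  cat(sprintf(
    "  costs (%s USD/yr): MDD %s, RBP %s, UBP %s, MDD-as-BD %s; screen $%s, eval $%s; discount %.0f%%\n",
    co$currency_year, format(co$c_mdd, big.mark = ","),
    format(co$c_rbp, big.mark = ","), format(co$c_ubp, big.mark = ","),
    format(co$c_mdd_as_bd, big.mark = ","), co$c_screen, co$c_eval,
    100 * co$discount
  ))
  invisible(x)
}

#' Size of the screened cohort
#'
#' The number of plan members newly diagnosed with MDD in one year:
#' `plan_size * mde_incidence * help_seeking`. Carried as an exact real number
#' internally; use `round = TRUE` for reporting in whole persons.
#'
#' @param params A [bd_params()] object.
#' @param round Round half-up to whole persons?
#' @return Cohort size (persons).
#' @export
target_cohort <- function(params, round = FALSE) {
  stopifnot(inherits(params, "bd_params"))
  n0 <- params$epi$plan_size * params$epi$mde_incidence * params$epi$help_seeking
  if (round) round_half_up(n0) else n0
}

#' Derive a target population size
#'
#' @param plan_size Health-plan membership (persons).
#' @param mde_incidence One-year incidence of a major depressive episode.
#' @param help_seeking Fraction of affected members who seek care.
#' @return Whole persons (rounded half-up).
#' @examples
#' target_population(1e6, 0.03, 0.50) # 15000
#' @export
target_population <- function(plan_size, mde_incidence, help_seeking) {
  check_positive(plan_size, "plan_size")
  check_prob(mde_incidence, "mde_incidence")
  check_prob(help_seeking, "help_seeking")
  if (mde_incidence <= 0) abort_field("mde_incidence", "must be positive")
  if (help_seeking <= 0) abort_field("help_seeking", "must be positive")
  round_half_up(plan_size * mde_incidence * help_seeking)
}

#' Adjust a historical cost for inflation
#'
#' Multiplies a cost by a user-supplied inflation factor and rounds to the
#' nearest dollar. No price index is looked up; the factor is an input.
#'
#' @param cost Cost in the source year's dollars (non-negative).
#' @param factor Inflation factor (positive).
#' @return Adjusted cost, nearest dollar.
#' @examples
#' inflation_adjust(7020, 11760 / 7020) # 11760
#' @export
inflation_adjust <- function(cost, factor) {
  check_nonneg(cost, "cost")
  check_number(factor, "factor")
  if (factor <= 0) abort_field("factor", "must be positive")
  round_half_up(cost * factor)
}

#' Update parameters by field name
#'
#' Applies named overrides to a `bd_params` object and re-validates. Field
#' names are the flat names used by [bd_params()] (e.g. `ubp_prevalence`,
#' `c_ubp`). If `c_mdd_as_bd` was left at its default it continues to track
#' `c_ubp` unless overridden explicitly.
#'
#' @param params A [bd_params()] object.
#' @param ... Named scalar overrides.
#' @return A new validated `bd_params` object.
#' @examples
#' bd_params() |> bd_params_update(ubp_prevalence = 0.11)
#' @export
bd_params_update <- function(params, ...) {
  stopifnot(inherits(params, "bd_params"))
  overrides <- list(...)
  if (length(overrides) == 0L) return(params)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    abort_field("...", "overrides must all be named")
  }
  flat <- c(params$epi, params$costs)
  unknown <- setdiff(nms, names(flat))
  if (length(unknown) > 0L) {
    abort_field(unknown[[1L]], "is not a model parameter")
  }
  flat[nms] <- overrides
  follows <- isTRUE(attr(params, "mdd_as_bd_follows_ubp")) &&
    !("c_mdd_as_bd" %in% nms)
  if (follows) flat$c_mdd_as_bd <- NULL
  do.call(bd_params, flat)
}

# Flat named list of all parameter fields, used for serialisation and diffing.
params_flatten <- function(params) {
  c(params$epi, params$costs)
}

#' Read and write model parameters as YAML
#'
#' The configuration file has two sections, `epi` and `costs`, whose keys are
#' the field names of [bd_params()]. Absent fields take the base-case
#' defaults; unknown keys and out-of-range values are rejected with an error
#' naming the field. `write_bd_params()` then `read_bd_params()` round-trips
#' all values exactly.
#'
#' @param path Path to a YAML file.
#' @param params A [bd_params()] object.
#' @return `read_bd_params()` returns a `bd_params` object;
#'   `write_bd_params()` returns `path` invisibly.
#' @export
read_bd_params <- function(path) {
  if (!file.exists(path)) abort_field("path", sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort_field("path", "must parse to a YAML mapping")
  unknown_top <- setdiff(names(raw), c("epi", "costs"))
  if (length(unknown_top) > 0L) {
    abort_field(unknown_top[[1L]], "is not a configuration section (use `epi` or `costs`)")
  }
  defaults <- bd_params()
  fields <- list(epi = names(defaults$epi), costs = names(defaults$costs))
  flat <- list()
  for (section in names(fields)) {
    given <- raw[[section]]
    if (is.null(given)) next
    unknown <- setdiff(names(given), fields[[section]])
    if (length(unknown) > 0L) {
      abort_field(paste0(section, ".", unknown[[1L]]), "is not a model parameter")
    }
    flat <- c(flat, given)
  }
  do.call(bd_params, flat)
}

#' @rdname read_bd_params
#' @export
write_bd_params <- function(params, path) {
  stopifnot(inherits(params, "bd_params"))
  yaml::write_yaml(list(epi = params$epi, costs = params$costs), path)
  invisible(path)
}
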