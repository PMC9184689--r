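#' Net benefit of a screening rule at a threshold probability
#'
#' The standard decision-curve statistic: at threshold probability `pt`, a
#' rule with the given operating point applied in a population with case
#' prevalence `p` has net benefit
#' `sens * p - (1 - spec) * (1 - p) * pt / (1 - pt)`
#' true positives per patient, after charging each false positive the odds of
#' the threshold.
#'
#' @param sens,spec Operating point (vectorised).
#' @param p Case prevalence.
#' @param pt Threshold probability, strictly in (0, 1) (vectorised).
#' @return Net benefit per patient (dimensionless).
#' @examples
#' net_benefit(0.87, 0.81, 0.16, 0.20)
#' @export
net_benefit <- function(sens, spec, p, pt) {
  if (!is.numeric(pt) || any(!is.finite(pt)) || any(pt <= 0) || any(pt >= 1)) {
    abort_field("pt", "must lie strictly in (0, 1)")
  }
  if (any(sens < 0 | sens > 1)) abort_field("sens", "must lie in [0, 1]")
  if (any(spec < 0 | spec > 1)) abort_field("spec", "must lie in [0, 1]")
  check_prob(p, "p")
  sens * p - (1 - spec) * (1 - p) * pt / (1 - pt)
}

#' Decision curve for a test profile
#'
#' Net benefit of the screening model, of treating everyone as bipolar
#' (`nb_all`), and of treating no one (`nb_none`, identically zero) across a
#' grid of threshold probabilities. The model's score cutoff is read as a
#' predicted probability: each threshold uses the profile row whose cutoff is
#' nearest to it (the profiles generated here share the 0-1 cutoff axis).
#'
#' @param profile A [bd_profile()] cutoff table.
#' @param p Case prevalence.
#' @param thresholds Threshold-probability grid in (0, 1).
#' @return A `bd_decision_curve` tibble with columns `pt`, `cutoff`,
#'   `nb_model`, `nb_all`, `nb_none`.
#' @examples
#' pop <- simulate_scores(2000, 0.16, 0.92, seed = 1)
#' curve <- decision_curve(operating_points(pop), p = 0.16)
#' @export
decision_curve <- function(profile, p, thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(inherits(profile, "bd_profile"))
  check_prob(p, "p")
  if (length(thresholds) == 0L || any(!is.finite(thresholds)) ||
      any(thresholds <= 0) || any(thresholds >= 1)) {
    abort_field("thresholds", "must lie strictly in (0, 1)")
  }
  idx <- vapply(thresholds, function(pt) which.min(abs(profile$cutoff - pt)),
                integer(1))
  out <- tibble::tibble(
    pt = as.numeric(thresholds),
    cutoff = profile$cutoff[idx],
    nb_model = net_benefit(profile$sensitivity[idx], profile$specificity[idx],
                           p, thresholds),
    nb_all = net_benefit(1, 0, p, thresholds),
    nb_none = 0
  )
  structure(out, class = c("bd_decision_curve", class(tibble::tibble())),
            prevalence = p, profile_name = attr(profile, "profile_name"))
}
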