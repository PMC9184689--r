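#' Expected confusion counts for a screened cohort
#'
#' Splits a cohort of size `n0` with case prevalence `p` by the operating
#' characteristics of the screen. Counts are expectations (real numbers), not
#' sampled integers.
#'
#' @param n0 Cohort size (persons, positive).
#' @param p Case prevalence in the cohort.
#' @param sens,spec Sensitivity and specificity of the screen.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_counts(15000, 0.16, 0.87, 0.81)
#' @export
confusion_counts <- function(n0, p, sens, spec) {
  check_positive(n0, "n0")
  check_prob(p, "p")
  check_prob(sens, "sens")
  check_prob(spec, "spec")
  tibble::tibble(
    tp = n0 * p * sens,
    fp = n0 * (1 - p) * (1 - spec),
    fn = n0 * p * (1 - sens),
    tn = n0 * (1 - p) * spec
  )
}

#' Predictive values of a screen at a given prevalence
#'
#' @inheritParams confusion_counts
#' @return A one-row tibble with columns `ppv`, `npv`.
#' @examples
#' ppv_npv(0.87, 0.81, 0.16) # ~0.46, ~0.97
#' @export
ppv_npv <- function(sens, spec, p) {
  check_prob(sens, "sens")
  check_prob(spec, "spec")
  check_prob(p, "p")
  pos <- p * sens + (1 - p) * (1 - spec)
  neg <- (1 - p) * spec + p * (1 - sens)
  if (pos <= 0) {
    abort_field("sens", "and spec give no positive calls: PPV undefined",
                class = "bdscreen_undefined_value")
  }
  if (neg <= 0) {
    abort_field("sens", "and spec give no negative calls: NPV undefined",
                class = "bdscreen_undefined_value")
  }
  tibble::tibble(ppv = p * sens / pos, npv = (1 - p) * spec / neg)
}

#' One-time screening cascade
#'
#' Applies a one-time screen at the given operating point to the incident MDD
#' cohort and routes patients to their post-screen diagnostic state. Every
#' screen-positive is provisionally labelled bipolar; a fraction
#' `referral_prob` of positives sees a psychiatrist who assigns the true
#' diagnosis with probability `psych_accuracy`. Consequently true positives
#' end up recognised bipolar (RBP) whether referred or not, referred false
#' positives are returned to a correct MDD label, unreferred false positives
#' keep the wrong bipolar label (MDD-as-BD), false negatives stay unrecognised
#' (UBP), and true negatives stay correctly diagnosed MDD. One-time costs are
#' screening for everyone plus an evaluation fee per referral, charged at time
#' zero (undiscounted).
#'
#' @param params A [bd_params()] object.
#' @param sens,spec Operating point of the screen.
#' @return A `bd_screen_outcome`: a one-row tibble with the confusion counts,
#'   `n_evaluated`, `one_time_cost`, and post-screen state counts `rbp0`,
#'   `ubp0`, `mdd_as_bd0`, `mdd0`.
#' @examples
#' apply_cascade(bd_params(), sens = 0.87, spec = 0.81)
#' @export
apply_cascade <- function(params, sens, spec) {
  stopifnot(inherits(params, "bd_params"))
  check_prob(sens, "sens")
  check_prob(spec, "spec")
  e <- params$epi
  co <- params$costs
  n0 <- target_cohort(params)
  cc <- confusion_counts(n0, e$ubp_prevalence, sens, spec)
  pi_ref <- e$referral_prob
  acc <- e$psych_accuracy

  rbp0 <- cc$tp * (1 - pi_ref) + cc$tp * pi_ref * acc
  ubp0 <- cc$fn + cc$tp * pi_ref * (1 - acc)
  mdd0 <- cc$tn + cc$fp * pi_ref * acc
  mdd_as_bd0 <- cc$fp * (1 - pi_ref) + cc$fp * pi_ref * (1 - acc)
  n_evaluated <- pi_ref * (cc$tp + cc$fp)
  one_time_cost <- n0 * co$c_screen + n_evaluated * co$c_eval

  out <- tibble::tibble(
    tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
    n_evaluated = n_evaluated,
    one_time_cost = one_time_cost,
    rbp0 = rbp0, ubp0 = ubp0, mdd_as_bd0 = mdd_as_bd0, mdd0 = mdd0
  )
  structure(out, class = c("bd_screen_outcome", class(out)),
            sens = sens, spec = spec, n0 = n0)
}
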