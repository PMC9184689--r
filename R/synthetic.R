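#' Case-mean shift of a binormal score model with a given AUC
#'
#' Under the equal-variance binormal model (control scores N(0,1), case scores
#' N(mu,1)) the area under the ROC curve is `pnorm(mu / sqrt(2))`, so the
#' separation that yields a target AUC is `mu = sqrt(2) * qnorm(auc)`.
#'
#' @param auc Target area under the ROC curve, in `[0.5, 1)`.
#' @return The case-mean shift `mu` (standard deviations).
#' @examples
#' binormal_separation(0.92) # ~1.987
#' @export
binormal_separation <- function(auc) {
  check_number(auc, "auc")
  if (auc < 0.5 || auc >= 1) abort_field("auc", "must lie in [0.5, 1)")
  sqrt(2) * stats::qnorm(auc)
}

#' @rdname binormal_separation
#' @param mu Case-mean shift (standard deviations).
#' @export
binormal_auc <- function(mu) {
  check_number(mu, "mu")
  stats::pnorm(mu / sqrt(2))
}

#' Simulate a labelled score population
#'
#' Draws a population of screening scores from the equal-variance binormal
#' model: each person is a case (unrecognised bipolar disorder) with
#' probability `prevalence`; latent scores are N(0,1) for controls and
#' N(mu,1) for cases, with `mu` chosen so the model's AUC equals `auc`.
#' Scores are reported as the calibrated posterior probability of being a
#' case given the latent score and the prevalence, like the predicted
#' probability of a well-calibrated classifier. The transform is strictly
#' monotone in the latent, so ROC operating characteristics and the AUC are
#' unchanged, while cutoffs on the usual 0.01-0.99 grid are directly
#' interpretable as threshold probabilities (as decision curve analysis
#' assumes).
#'
#' @param n Population size (>= 10).
#' @param prevalence Case fraction in (0, 1).
#' @param auc Target AUC in `[0.5, 1)`.
#' @param seed Integer seed; the same seed reproduces the population exactly.
#' @return A `bd_population` tibble with columns `label` (factor
#'   case/control) and `score`, and attributes `auc_target`, `prevalence`,
#'   `mu`, `seed`.
#' @examples
#' pop <- simulate_scores(2000, prevalence = 0.16, auc = 0.92, seed = 1)
#' empirical_auc(pop$score, pop$label)
#' @export
simulate_scores <- function(n, prevalence, auc, seed) {
  check_count(n, "n", min = 10)
  check_number(prevalence, "prevalence")
  if (prevalence <= 0 || prevalence >= 1) {
    abort_field("prevalence", "must lie strictly in (0, 1)")
  }
  mu <- binormal_separation(auc)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)

  draws <- withr::with_seed(seed, {
    is_case <- stats::runif(n) < prevalence
    latent <- stats::rnorm(n, mean = ifelse(is_case, mu, 0), sd = 1)
    list(is_case = is_case, latent = latent)
  })
  if (!any(draws$is_case) || all(draws$is_case)) {
    abort_field("n", "gave a degenerate population (no cases or no controls); increase n")
  }

  # Calibrated posterior P(case | latent z): logit(score) =
  # logit(prevalence) + mu*z - mu^2/2, strictly increasing in z.
  out <- tibble::tibble(
    label = factor(ifelse(draws$is_case, "case", "control"),
                   levels = c("control", "case")),
    score = stats::plogis(stats::qlogis(prevalence) +
                            mu * draws$latent - mu^2 / 2)
  )
  structure(out,
    class = c("bd_population", class(out)),
    auc_target = auc, prevalence = prevalence, mu = mu, seed = seed
  )
}

#' Empirical AUC by the rank-sum identity
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Logical, or a factor/character vector with cases marked
#'   `"case"`.
#' @return The Mann-Whitney estimate of the AUC (ties count 1/2).
#' @export
empirical_auc <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) labels <- labels == "case"
  if (!is.logical(labels) || length(labels) != length(scores)) {
    abort_field("labels", "must be logical or case/control, same length as scores")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) abort_field("labels", "needs at least one case and one control")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Sensitivity/specificity of the rule "score >= cutoff -> positive" at each
# cutoff of a sorted grid. Ties go to positive.
sens_spec_at <- function(case_scores, control_scores, cutoffs) {
  list(
    sensitivity = vapply(cutoffs, function(c) mean(case_scores >= c), numeric(1)),
    specificity = vapply(cutoffs, function(c) mean(control_scores < c), numeric(1))
  )
}

#' Tabulate a test profile from a score population
#'
#' Computes sensitivity and specificity of the rule "score >= cutoff is
#' positive" at each cutoff of a grid, optionally with percentile-bootstrap
#' 95% confidence intervals over resampled (label, score) pairs. This emulates
#' the cutoff tables a validated screening instrument publishes.
#'
#' @param population A [simulate_scores()] tibble, or any data frame with
#'   columns `label` and `score`.
#' @param cutoffs Strictly increasing score thresholds. Defaults to the
#'   0.01-0.99 grid (step 0.01) matching probability-scale scores.
#' @param n_boot Bootstrap replicates for the CIs; 0 disables them.
#' @param seed Integer seed for the bootstrap (a deterministic child stream;
#'   defaults to the population's own seed when present).
#' @param name Profile label, e.g. the instrument's name.
#' @return A `bd_profile` tibble with columns `cutoff`, `sensitivity`,
#'   `specificity` and (when `n_boot > 0`) `sens_lo`, `sens_hi`, `spec_lo`,
#'   `spec_hi`.
#' @examples
#' pop <- simulate_scores(2000, 0.16, 0.92, seed = 1)
#' operating_points(pop, cutoffs = seq(0.1, 0.9, 0.1))
#' @export
operating_points <- function(population, cutoffs = seq(0.01, 0.99, by = 0.01),
                             n_boot = 0, seed = NULL, name = "synthetic") {
  if (!is.data.frame(population) ||
      !all(c("label", "score") %in% names(population))) {
    abort_field("population", "must be a data frame with columns `label` and `score`")
  }
  if (length(cutoffs) == 0L || any(!is.finite(cutoffs))) {
    abort_field("cutoffs", "must be non-empty and finite")
  }
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    abort_field("cutoffs", "must be strictly increasing")
  }
  n_boot <- check_count(n_boot, "n_boot", min = 0)
  is_case <- population$label == "case"
  case_scores <- population$score[is_case]
  control_scores <- population$score[!is_case]
  if (length(case_scores) == 0L || length(control_scores) == 0L) {
    abort_field("population", "needs at least one case and one control")
  }

  point <- sens_spec_at(case_scores, control_scores, cutoffs)
  out <- tibble::tibble(
    cutoff = as.numeric(cutoffs),
    sensitivity = point$sensitivity,
    specificity = point$specificity
  )

  if (n_boot > 0) {
    if (is.null(seed)) seed <- attr(population, "seed")
    if (is.null(seed)) abort_field("seed", "is required when n_boot > 0 and the population carries no seed")
    seed <- check_count(seed, "seed", min = -.Machine$integer.max)
    boot_seed <- (as.double(seed) * 69069 + 12345) %% 2147483647
    scores <- population$score
    n <- length(scores)
    boots <- withr::with_seed(as.integer(boot_seed), {
      lapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        ic <- is_case[idx]
        if (!any(ic) || all(ic)) return(NULL) # degenerate resample: drop
        sens_spec_at(scores[idx][ic], scores[idx][!ic], cutoffs)
      })
    })
    boots <- boots[!vapply(boots, is.null, logical(1))]
    sens_mat <- matrix(vapply(boots, `[[`, numeric(length(cutoffs)), "sensitivity"),
                       nrow = length(cutoffs))
    spec_mat <- matrix(vapply(boots, `[[`, numeric(length(cutoffs)), "specificity"),
                       nrow = length(cutoffs))
    qs <- function(m, p) apply(m, 1, stats::quantile, probs = p, names = FALSE)
    out$sens_lo <- qs(sens_mat, 0.025)
    out$sens_hi <- qs(sens_mat, 0.975)
    out$spec_lo <- qs(spec_mat, 0.025)
    out$spec_hi <- qs(spec_mat, 0.975)
  }

  new_bd_profile(out, name = name)
}

# Constructor + invariant checks for a cutoff table.
new_bd_profile <- function(tbl, name) {
  tbl <- tibble::as_tibble(tbl)
  if (is.unsorted(tbl$cutoff, strictly = TRUE)) {
    abort_field("cutoff", "must be strictly increasing")
  }
  purrr::walk(tbl$sensitivity, check_prob, name = "sensitivity")
  purrr::walk(tbl$specificity, check_prob, name = "specificity")
  if (is.unsorted(rev(tbl$sensitivity))) {
    abort_field("sensitivity", "must be non-increasing in the cutoff")
  }
  if (is.unsorted(tbl$specificity)) {
    abort_field("specificity", "must be non-decreasing in the cutoff")
  }
  structure(tbl, class = c("bd_profile", class(tibble::tibble())),
            profile_name = name)
}

#' Build a test profile from explicit operating points
#'
#' @param cutoff,sensitivity,specificity Equal-length numeric vectors;
#'   cutoffs strictly increasing, sensitivity non-increasing and specificity
#'   non-decreasing in the cutoff.
#' @param name Profile label.
#' @return A `bd_profile` tibble.
#' @examples
#' bd_profile(c(0.2, 0.5, 0.8), c(0.95, 0.80, 0.40), c(0.50, 0.85, 0.99))
#' @export
bd_profile <- function(cutoff, sensitivity, specificity, name = "test") {
  if (length(cutoff) != length(sensitivity) ||
      length(cutoff) != length(specificity)) {
    abort_field("cutoff", "sensitivity and specificity must have the same length")
  }
  new_bd_profile(
    tibble::tibble(cutoff = as.numeric(cutoff),
                   sensitivity = as.numeric(sensitivity),
                   specificity = as.numeric(specificity)),
    name = name
  )
}

#' Read or write a test profile as CSV
#'
#' The delimited format (columns `cutoff, sensitivity, specificity` and
#' optionally `sens_lo, sens_hi, spec_lo, spec_hi`) is also the ingestion
#' format for operating-point tables transcribed from a published instrument.
#'
#' @param path CSV file path.
#' @param profile A `bd_profile` tibble.
#' @param name Profile label to attach on read (defaults to the file name).
#' @return `read_profile()` returns a `bd_profile`; `write_profile()` returns
#'   `path` invisibly.
#' @export
read_profile <- function(path, name = NULL) {
  if (!file.exists(path)) abort_field("path", sprintf("file not found: %s", path))
  tbl <- utils::read.csv(path)
  need <- c("cutoff", "sensitivity", "specificity")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0L) abort_field(missing[[1L]], "column is required")
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  new_bd_profile(tbl, name = name)
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "bd_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
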