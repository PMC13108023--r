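#' Expected number of affected newborns
#'
#' @param births Size of the birth cohort (positive).
#' @param prevalence Per-birth probability of infantile-onset Pompe disease,
#'   strictly between 0 and 1.
#' @return The real-valued expected case count `births * prevalence`
#'   (not rounded).
#' @examples
#' expected_cases(727288, 1 / 297387) # ~2.45 cases
#' @export
expected_cases <- function(births, prevalence) {
  stopifnot(births > 0, prevalence > 0, prevalence < 1)
  births * prevalence
}

#' Screening decision-tree cascade
#'
#' Classifies the birth cohort through the screening decision tree and
#' totals the screening-program costs.  Under the screening strategy every
#' newborn receives the initial dried-blood-spot assay; the recalled
#' fraction is re-tested; a proportion of recalls proceeds to confirmatory
#' genetic testing.  True positives are assumed to be contained within the
#' recall fraction and always complete confirmatory testing, so the
#' confirmatory count is floored at the expected case count.  The
#' comparator arm runs no program and accrues no cascade cost.
#'
#' @param params A `pompe_params` object.
#' @param arm `"NBS"` (screening) or `"NoNBS"` (clinical identification).
#' @return One-row tibble: `arm`, `n_iopd_expected`, `n_recalled`,
#'   `n_confirmatory`, `cost_initial_screen`, `cost_retests`,
#'   `cost_confirmatory`, `cost_total` (JPY).
#' @examples
#' cascade(cea_parameters(), "NBS")$cost_initial_screen # 2.18 billion JPY
#' @export
cascade <- function(params, arm = c("NBS", "NoNBS")) {
  params <- validate_parameters(params)
  arm <- match.arg(arm)
  n_cases <- expected_cases(params$births, params$prevalence)
  if (arm == "NBS") {
    n_recalled <- params$births * params$retest_rate
    n_true_pos <- n_cases * params$sensitivity
    n_confirmatory <- max(n_recalled * params$confirm_proportion, n_true_pos)
    cost_initial <- params$births * params$cost_screen
    cost_retests <- n_recalled * params$cost_retest
    cost_confirm <- n_confirmatory * params$cost_genetic
  } else {
    n_recalled <- 0
    n_confirmatory <- 0
    cost_initial <- 0
    cost_retests <- 0
    cost_confirm <- 0
  }
  tibble::tibble(
    arm = arm,
    n_iopd_expected = n_cases,
    n_recalled = n_recalled,
    n_confirmatory = n_confirmatory,
    cost_initial_screen = cost_initial,
    cost_retests = cost_retests,
    cost_confirmatory = cost_confirm,
    cost_total = cost_initial + cost_retests + cost_confirm
  )
}
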