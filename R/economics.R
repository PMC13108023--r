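#' Discount factor
#'
#' @param rate Annual discount rate (>= 0); costs and benefits share it.
#' @param t_years Time from model start in years.
#' @return `(1 + rate)^(-t_years)`.
#' @examples
#' discount_factor(0.02, 1)
#' @export
discount_factor <- function(rate, t_years) {
  stopifnot(rate >= 0, all(t_years >= 0))
  (1 + rate)^(-t_years)
}

# reference norm = mean over the 16-19-year band (generator makes the band
# constant; user tables must cover it)
qol_reference <- function(qol_norms) {
  ref_rows <- qol_norms$age_years >= 16 & qol_norms$age_years <= 19
  if (!any(ref_rows)) {
    stop("QOL norm table must cover the 16-19-year reference band",
         call. = FALSE)
  }
  mean(qol_norms$norm[ref_rows])
}

qol_factor_at <- function(qol_norms, ages) {
  ref <- qol_reference(qol_norms)
  ages <- pmin(ages, 89) # ages 90+ take the 80-89 band value
  ages <- pmin(ages, max(qol_norms$age_years))
  idx <- match(ages, qol_norms$age_years)
  if (anyNA(idx)) stop("QOL norm table does not cover all requested ages",
                       call. = FALSE)
  qol_norms$norm[idx] / ref
}

#' Age-adjusted health-state utility
#'
#' Scales a health-state utility by the ratio of the population norm at the
#' attained age to the norm in the 16--19-year reference band.  Ages 90 and
#' over use the 80--89-year band value.
#'
#' @param state_utility Utility weight of the health state in \[0, 1\].
#' @param age_years Attained age(s), integer years.
#' @param qol_norms Tibble `age_years`, `norm`.
#' @return Adjusted utility (vectorised over `age_years`).
#' @examples
#' utility_at_age(0.75, 17, make_qol_norms()) # reference band: unchanged
#' @export
utility_at_age <- function(state_utility, age_years, qol_norms) {
  state_utility * qol_factor_at(qol_norms, floor(age_years))
}

#' Enzyme-replacement drug cost per model cycle
#'
#' Weight-based dosing with whole-vial rounding per infusion (no vial
#' sharing): `vials = ceiling(weight * dose_mg_per_kg / vial_mg)`; the
#' number of infusions per cycle follows from the infusion interval
#' (365.25-day year), e.g. ~13.04 per 6-month cycle at 2-week intervals.
#'
#' @param age_years Attained age(s), integer years.
#' @param weight Tibble `age_years`, `weight_kg`.
#' @param params A `pompe_params` object.
#' @return JPY per cycle (vectorised over `age_years`).
#' @export
drug_cost_per_cycle <- function(age_years, weight, params) {
  age <- pmin(floor(age_years), max(weight$age_years))
  idx <- match(age, weight$age_years)
  if (anyNA(idx)) stop("weight table does not cover all requested ages",
                       call. = FALSE)
  kg <- weight$weight_kg[idx]
  vials <- ceiling(kg * params$dose_mg_per_kg / params$vial_mg)
  infusions <- (365.25 / 7) * params$cycle_years / params$infusion_interval_weeks
  vials * params$vial_price * infusions
}

# effective occupancy rows used for rewards: cycle-start membership, or the
# within-cycle average under the half-cycle correction
reward_occupancy <- function(trace, params) {
  occ <- trace_matrix(trace)
  n_cycles <- nrow(occ) - 1
  if (identical(params$half_cycle, "half-cycle")) {
    (occ[seq_len(n_cycles), , drop = FALSE] +
       occ[seq_len(n_cycles) + 1, , drop = FALSE]) / 2
  } else {
    occ[seq_len(n_cycles), , drop = FALSE]
  }
}

#' Accrue discounted outcomes and costs for an affected patient
#'
#' Walks a cohort trace cycle by cycle, crediting each cycle's rewards to
#' the occupancy at the cycle start (or the within-cycle average under the
#' half-cycle correction), discounted at the cycle-start time.  Life-years
#' accrue in all alive states; QALYs weight them by age-adjusted
#' health-state utilities; management and drug costs accrue in all alive
#' states (all patients are on enzyme replacement therapy), ventilation
#' cost additionally in the ventilator state.  In the clinically identified
#' arm the first cycle's drug cost is scaled by the fraction of the cycle
#' remaining after the treatment-initiation delay.
#'
#' @param trace A `cohort_trace` for the affected cohort.
#' @param params A `pompe_params` object.
#' @param bundle Input bundle (`qol_norms`, `weight`).
#' @param arm `"NBS"` or `"NoNBS"` (controls the drug-start delay).
#' @return One-row tibble: `arm`, `ly`, `qaly`, `cost_mgmt`, `cost_vent`,
#'   `cost_drug`, `cost_total`, all discounted, per patient.
#' @export
accrue <- function(trace, params, bundle, arm = c("NBS", "NoNBS")) {
  arm <- match.arg(arm)
  occ <- reward_occupancy(trace, params)
  n_cycles <- nrow(occ)
  k <- 0:(n_cycles - 1)
  t_k <- k * params$cycle_years
  age <- floor(t_k)
  df <- discount_factor(params$discount_rate, t_k)
  cycle_months <- params$cycle_years * 12

  alive <- occ[, "no_walk"] + occ[, "walk"] + occ[, "vent"]
  qfac <- qol_factor_at(bundle$qol_norms, age)
  ly <- sum(df * alive * params$cycle_years)
  qaly <- sum(df * params$cycle_years * qfac *
                (occ[, "no_walk"] * params$utility_no_walk +
                 occ[, "walk"] * params$utility_walk +
                 occ[, "vent"] * params$utility_vent))

  cost_mgmt <- sum(df * alive * params$cost_mgmt_month * cycle_months)
  cost_vent <- sum(df * occ[, "vent"] * params$cost_vent_month * cycle_months)
  drug_frac <- rep(1, n_cycles)
  if (arm == "NoNBS") {
    drug_frac[1] <- max(cycle_months - params$treatment_delay_months, 0) /
      cycle_months
  }
  cost_drug <- sum(df * alive * drug_cost_per_cycle(t_k, bundle$weight, params) *
                     drug_frac)

  tibble::tibble(
    arm = arm, ly = ly, qaly = qaly,
    cost_mgmt = cost_mgmt, cost_vent = cost_vent, cost_drug = cost_drug,
    cost_total = cost_mgmt + cost_vent + cost_drug
  )
}

#' Discounted outcomes for an unaffected newborn
#'
#' General-population members survive under the background life table,
#' accrue the age-adjusted population utility, and incur no modelled
#' medical cost.
#'
#' @param params A `pompe_params` object.
#' @param bundle Input bundle (`life_table`, `qol_norms`).
#' @param n_cycles Cycles to run; defaults to the full horizon.
#' @return One-row tibble `ly`, `qaly` (discounted, per person).
#' @export
genpop_outcome <- function(params, bundle, n_cycles = NULL) {
  if (is.null(n_cycles)) n_cycles <- n_model_cycles(params)
  k <- 0:(n_cycles - 1)
  t_k <- k * params$cycle_years
  age <- floor(t_k)
  p_cycle <- annual_prob_to_cycle(
    lifetable_annual_prob(bundle$life_table, age), params$cycle_years)
  surv <- cumprod(c(1, 1 - p_cycle)) # survival at cycle starts 0..n
  occ <- if (identical(params$half_cycle, "half-cycle")) {
    (surv[k + 1] + surv[k + 2]) / 2
  } else {
    surv[k + 1]
  }
  df <- discount_factor(params$discount_rate, t_k)
  qfac <- qol_factor_at(bundle$qol_norms, age)
  tibble::tibble(
    ly = sum(df * occ * params$cycle_years),
    qaly = sum(df * occ * params$cycle_years * qfac * params$utility_genpop)
  )
}

#' Prevalence-weighted per-infant outcomes for one strategy
#'
#' Mixes the affected-patient and general-population outcomes by
#' prevalence and spreads the screening-cascade costs over the whole birth
#' cohort.
#'
#' @param patient One-row tibble from [accrue()].
#' @param genpop One-row tibble from [genpop_outcome()].
#' @param cascade_result One-row tibble from [cascade()] for the same arm.
#' @param params A `pompe_params` object.
#' @return One-row tibble: `arm`, `ly`, `qaly`, cost components
#'   (`cost_screening`, `cost_genetic`, `cost_mgmt`, `cost_vent`,
#'   `cost_drug`) and `cost_total`, all per infant.
#' @export
per_infant_mix <- function(patient, genpop, cascade_result, params) {
  prev <- params$prevalence
  cost_screening <- (cascade_result$cost_initial_screen +
                       cascade_result$cost_retests) / params$births
  cost_genetic <- cascade_result$cost_confirmatory / params$births
  out <- tibble::tibble(
    arm = patient$arm,
    ly = prev * patient$ly + (1 - prev) * genpop$ly,
    qaly = prev * patient$qaly + (1 - prev) * genpop$qaly,
    cost_screening = cost_screening,
    cost_genetic = cost_genetic,
    cost_mgmt = prev * patient$cost_mgmt,
    cost_vent = prev * patient$cost_vent,
    cost_drug = prev * patient$cost_drug
  )
  out$cost_total <- out$cost_screening + out$cost_genetic + out$cost_mgmt +
    out$cost_vent + out$cost_drug
  out
}

#' Incremental cost-effectiveness ratios
#'
#' Computes screened-minus-comparator increments on unrounded per-infant
#' values and the resulting ICERs per QALY and per life-year.  When cost
#' and effect increments have opposite signs the ratio is meaningless and a
#' dominance flag is set instead (`"dominant"`: cheaper and more effective;
#' `"dominated"`: costlier and less effective); a zero effect increment
#' yields an undefined ICER with flag `"zero-effect"`.
#'
#' @param per_infant Two-row tibble of per-infant strategy outcomes with
#'   arms `"NBS"` and `"NoNBS"`.
#' @return List: `inc_cost`, `inc_qaly`, `inc_ly`, `icer_qaly`, `icer_ly`,
#'   `dominance`.
#' @export
icer <- function(per_infant) {
  nbs <- per_infant[per_infant$arm == "NBS", ]
  ref <- per_infant[per_infant$arm == "NoNBS", ]
  stopifnot(nrow(nbs) == 1, nrow(ref) == 1)
  inc_cost <- nbs$cost_total - ref$cost_total
  inc_qaly <- nbs$qaly - ref$qaly
  inc_ly <- nbs$ly - ref$ly

  ratio_or_na <- function(dc, de) if (de != 0) dc / de else NA_real_
  dominance <- if (inc_qaly == 0) {
    "zero-effect"
  } else if (inc_cost < 0 && inc_qaly > 0) {
    "dominant"
  } else if (inc_cost > 0 && inc_qaly < 0) {
    "dominated"
  } else {
    "none"
  }
  list(
    inc_cost = inc_cost, inc_qaly = inc_qaly, inc_ly = inc_ly,
    icer_qaly = if (dominance == "none") ratio_or_na(inc_cost, inc_qaly) else NA_real_,
    icer_ly = if (dominance == "none") ratio_or_na(inc_cost, inc_ly) else NA_real_,
    dominance = dominance
  )
}

#' Run the full cost-effectiveness analysis
#'
#' End-to-end pipeline: screening cascade for both strategies, per-cycle
#' transition schedules, Markov cohort traces, discounted accrual for
#' affected patients and the general population, prevalence-weighted
#' per-infant mixing, and incremental cost-effectiveness ratios.
#'
#' @param params A `pompe_params` object (base case: [cea_parameters()]).
#' @param bundle Input bundle from [synthetic_bundle()] or [read_bundle()].
#' @param horizon_years Optional restricted horizon (e.g. 20); defaults to
#'   the lifetime horizon in `params`.
#' @return A `pompe_cea` object; see [tidy.pompe_cea()] and
#'   [glance.pompe_cea()] for tabular views.
#' @examples
#' res <- run_cea(cea_parameters(), synthetic_bundle())
#' glance(res)
#' @export
run_cea <- function(params = cea_parameters(), bundle = synthetic_bundle(),
                    horizon_years = NULL) {
  params <- validate_parameters(params)
  n_cycles <- n_model_cycles(params, horizon_years)

  cascades <- dplyr::bind_rows(cascade(params, "NBS"), cascade(params, "NoNBS"))
  genpop <- genpop_outcome(params, bundle, n_cycles)

  run_arm <- function(arm) {
    sched <- build_schedule(params, arm, bundle, n_cycles)
    trace <- run_cohort(sched)
    list(trace = trace, patient = accrue(trace, params, bundle, arm))
  }
  arms <- list(NBS = run_arm("NBS"), NoNBS = run_arm("NoNBS"))

  patient <- dplyr::bind_rows(arms$NBS$patient, arms$NoNBS$patient)
  per_infant <- dplyr::bind_rows(
    per_infant_mix(arms$NBS$patient, genpop,
                   cascades[cascades$arm == "NBS", ], params),
    per_infant_mix(arms$NoNBS$patient, genpop,
                   cascades[cascades$arm == "NoNBS", ], params)
  )
  inc <- icer(per_infant)

  structure(list(
    params = params,
    horizon_years = if (is.null(horizon_years)) params$horizon_years else horizon_years,
    cascades = cascades,
    patient = patient,
    genpop = genpop,
    per_infant = per_infant,
    increments = inc,
    traces = list(NBS = arms$NBS$trace, NoNBS = arms$NoNBS$trace)
  ), class = "pompe_cea")
}

#' @export
print.pompe_cea <- function(x, ...) {
  cat(sprintf("<pompe_cea> horizon %.0f y, discount %.1f%%/y\n",
              x$horizon_years, 100 * x$params$discount_rate))
  print(tidy(x))
  invisible(x)
}

#' Strategy-level results table
#'
#' One row per strategy in the conventional reporting layout: total
#' discounted QALYs and life-years per infant, cost per infant, increments
#' (screening minus comparator) and ICERs per life-year and per QALY.
#'
#' @param x A `pompe_cea` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pompe_cea
#' @export
tidy.pompe_cea <- function(x, ...) {
  pi <- x$per_infant
  inc <- x$increments
  is_nbs <- pi$arm == "NBS"
  tibble::tibble(
    strategy = pi$arm,
    total_qalys = pi$qaly,
    incremental_qalys = ifelse(is_nbs, inc$inc_qaly, NA_real_),
    total_lys = pi$ly,
    incremental_lys = ifelse(is_nbs, inc$inc_ly, NA_real_),
    cost_per_infant = pi$cost_total,
    incremental_cost = ifelse(is_nbs, inc$inc_cost, NA_real_),
    icer_per_ly = ifelse(is_nbs, inc$icer_ly, NA_real_),
    icer_per_qaly = ifelse(is_nbs, inc$icer_qaly, NA_real_)
  )
}

#' One-row summary of a cost-effectiveness analysis
#'
#' @param x A `pompe_cea` object.
#' @param ... Unused.
#' @return One-row tibble with increments, ICERs and the dominance flag.
#' @method glance pompe_cea
#' @export
glance.pompe_cea <- function(x, ...) {
  inc <- x$increments
  tibble::tibble(
    horizon_years = x$horizon_years,
    inc_cost = inc$inc_cost,
    inc_qaly = inc$inc_qaly,
    inc_ly = inc$inc_ly,
    icer_per_qaly = inc$icer_qaly,
    icer_per_ly = inc$icer_ly,
    dominance = inc$dominance
  )
}

#' Cost decomposition by strategy
#'
#' Cohort-level cost components (per-infant values scaled by the birth
#' cohort) with each component's share of the strategy total, e.g. the drug
#' share of total spending under each strategy.
#'
#' @param x A `pompe_cea` object.
#' @return Long tibble `arm`, `component`, `cost_cohort`, `share`.
#' @export
cea_cost_breakdown <- function(x) {
  stopifnot(inherits(x, "pompe_cea"))
  comps <- c("cost_screening", "cost_genetic", "cost_mgmt", "cost_vent",
             "cost_drug")
  long <- tidyr::pivot_longer(x$per_infant[, c("arm", comps)], -"arm",
                              names_to = "component", values_to = "per_infant")
  long |>
    dplyr::mutate(component = sub("^cost_", "", .data$component),
                  cost_cohort = .data$per_infant * x$params$births) |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(share = .data$cost_cohort / sum(.data$cost_cohort)) |>
    dplyr::ungroup() |>
    dplyr::select("arm", "component", "cost_cohort", "share")
}
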