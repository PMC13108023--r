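#' Kaplan--Meier curve container
#'
#' Validates a digitized survivor-function point list: first point at
#' (0, 1), strictly increasing times, survival non-increasing within
#' \[0, 1\].  The curve is interpreted as a right-continuous step function.
#'
#' @param points Data frame with columns `time_months`, `survival`.
#' @param label Optional label (e.g. `"overall"`, `"ventilation-free"`).
#' @return A `km_curve` tibble.
#' @export
km_curve <- function(points, label = NULL) {
  stopifnot(is.data.frame(points),
            all(c("time_months", "survival") %in% names(points)))
  pts <- tibble::as_tibble(points[c("time_months", "survival")])
  if (nrow(pts) == 0 || pts$time_months[1] != 0 || abs(pts$survival[1] - 1) > 1e-12) {
    stop("KM curve must start at (0, 1)", call. = FALSE)
  }
  if (is.unsorted(pts$time_months, strictly = TRUE)) {
    stop("KM curve times must be strictly increasing", call. = FALSE)
  }
  if (any(pts$survival < -1e-12) || any(pts$survival > 1 + 1e-12)) {
    stop("KM survival must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(pts$survival) > 1e-12)) {
    stop("KM survival must be non-increasing; repair with repair_km_curve()",
         call. = FALSE)
  }
  structure(pts, class = c("km_curve", class(pts)), label = label)
}

#' Monotone repair of a digitized curve
#'
#' Digitization introduces small upward wiggles; this projects the survival
#' column onto the nearest monotone non-increasing sequence via a running
#' minimum and reports (message) the largest correction applied.
#'
#' @param points Data frame with `time_months`, `survival`.
#' @param label Passed to [km_curve()].
#' @return A valid `km_curve`.
#' @export
repair_km_curve <- function(points, label = NULL) {
  s <- points$survival
  repaired <- cummin(pmin(pmax(s, 0), 1))
  delta <- max(abs(repaired - s))
  if (delta > 0) {
    message(sprintf("repair_km_curve: monotone projection moved points by up to %.4g", delta))
  }
  out <- points
  out$survival <- repaired
  out$survival[1] <- 1
  km_curve(out, label = label)
}

# step-function evaluation of a KM curve (right-continuous)
km_survival_at <- function(curve, times) {
  idx <- findInterval(times, curve$time_months)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

#' Convert an annual probability to a per-cycle probability
#'
#' Constant-rate conversion `1 - (1 - p)^cycle_years`.
#'
#' @param p_annual Annual event probability in \[0, 1\].
#' @param cycle_years Cycle length in years (> 0).
#' @return Per-cycle probability.
#' @examples
#' annual_prob_to_cycle(0.02, 0.5) # 0.01005...
#' @export
annual_prob_to_cycle <- function(p_annual, cycle_years) {
  stopifnot(all(p_annual >= 0), all(p_annual <= 1), cycle_years > 0)
  1 - (1 - p_annual)^cycle_years
}

#' Convert a constant hazard to a per-cycle probability
#'
#' Exponential-survival conversion `1 - exp(-h * cycle_years)`.
#'
#' @param h_per_year Hazard rate per year (>= 0).
#' @param cycle_years Cycle length in years.
#' @return Per-cycle event probability.
#' @examples
#' hazard_to_cycle_prob(0.0257, 0.5)
#' @export
hazard_to_cycle_prob <- function(h_per_year, cycle_years) {
  stopifnot(all(h_per_year >= 0), cycle_years > 0)
  1 - exp(-h_per_year * cycle_years)
}

#' Per-cycle conditional event probabilities from a KM curve
#'
#' For cycle k spanning `[k*cycle_months, (k+1)*cycle_months)` the
#' conditional event probability is `1 - S(t_end) / S(t_start)` with S the
#' right-continuous step function through the digitized points (extended
#' flat beyond the last point).  When `S(t_start) = 0` the risk set is
#' empty and the probability is defined as 0.
#'
#' @param curve A `km_curve`.
#' @param cycle_months Cycle length in months.
#' @param n_cycles Number of cycles to tabulate; defaults to the number of
#'   whole cycles the curve's support covers.
#' @return Numeric vector of per-cycle probabilities.
#' @export
km_interval_probs <- function(curve, cycle_months, n_cycles = NULL) {
  if (!inherits(curve, "km_curve")) curve <- km_curve(curve)
  stopifnot(cycle_months > 0)
  if (is.null(n_cycles)) {
    n_cycles <- floor(max(curve$time_months) / cycle_months)
  }
  if (n_cycles < 1) stop("curve support shorter than one cycle", call. = FALSE)
  bounds <- (0:n_cycles) * cycle_months
  s <- km_survival_at(curve, bounds)
  s_start <- s[-length(s)]
  s_end <- s[-1]
  ifelse(s_start <= 0, 0, 1 - s_end / s_start)
}

#' Per-cycle walking-acquisition probabilities
#'
#' Converts an unconditional cumulative walking schedule C(t) (proportion
#' of the treated cohort walking by age t months, step-interpolated) into
#' conditional per-cycle probabilities among surviving non-walkers:
#' `q_k = (C(t_end) - C(t_start)) / (1 - C(t_start))`, clamped to \[0, 1\].
#'
#' @param schedule Tibble with `age_months`, `cum_prop` (non-decreasing,
#'   <= 1), or an empty tibble / NULL for no walking.
#' @param cycle_months Cycle length in months.
#' @param n_cycles Number of cycles to tabulate.
#' @return Numeric vector of conditional probabilities, length `n_cycles`.
#' @export
walking_transition_probs <- function(schedule, cycle_months, n_cycles) {
  if (is.null(schedule) || nrow(schedule) == 0) return(rep(0, n_cycles))
  if (is.unsorted(schedule$cum_prop) || any(schedule$cum_prop > 1 + 1e-12)) {
    stop("walking schedule must be non-decreasing with proportions <= 1",
         call. = FALSE)
  }
  cum_at <- function(t) {
    idx <- findInterval(t, schedule$age_months)
    ifelse(idx == 0, 0, schedule$cum_prop[pmax(idx, 1)])
  }
  bounds <- (0:n_cycles) * cycle_months
  c_start <- cum_at(bounds[-length(bounds)])
  c_end <- cum_at(bounds[-1])
  q <- ifelse(1 - c_start <= 0, 0, (c_end - c_start) / (1 - c_start))
  pmin(pmax(q, 0), 1)
}

# life-table lookup: annual death probability at integer age, clamped to
# the closing row (where death is certain)
lifetable_annual_prob <- function(life_table, ages) {
  max_age <- max(life_table$age_years)
  ages <- pmin(ages, max_age)
  idx <- match(ages, life_table$age_years)
  if (anyNA(idx)) stop("life table does not cover all requested ages", call. = FALSE)
  life_table$p_death_annual[idx]
}

#' Per-cycle death probabilities for the screened arm
#'
#' Screened, promptly treated patients are assumed to experience no
#' mechanical ventilation and background general-population mortality only:
#' each cycle's death probability is the life-table annual probability at
#' the attained integer age, converted to the cycle length.
#'
#' @param life_table Tibble `age_years`, `p_death_annual`.
#' @param params A `pompe_params` object (cycle and horizon).
#' @param n_cycles Number of cycles; defaults to the full horizon.
#' @return Tibble `cycle`, `p_death_no_walk`, `p_death_walk`,
#'   `p_death_vent`, `p_vent_onset` (identically 0).
#' @export
build_nbs_mortality <- function(life_table, params, n_cycles = NULL) {
  if (is.null(n_cycles)) n_cycles <- n_model_cycles(params)
  k <- 0:(n_cycles - 1)
  age <- floor(k * params$cycle_years)
  p_bg <- annual_prob_to_cycle(lifetable_annual_prob(life_table, age),
                               params$cycle_years)
  tibble::tibble(
    cycle = k,
    p_death_no_walk = p_bg,
    p_death_walk = p_bg,
    p_death_vent = p_bg,
    p_vent_onset = 0
  )
}

#' Per-cycle death probabilities for the clinically identified arm
#'
#' Splices three mortality regimes, following the curve-derived evidence
#' window: (1) during the first `clinical_km_window_months` (48 by
#' default), conditional interval probabilities from the digitized
#' overall-survival curve, applied uniformly to all alive states (the
#' non-ambulatory and ventilator-dependent states share a single advanced
#' disease survival function); (2) from the window end to
#' `clinical_plateau_end_months` (138), age-matched general-population
#' mortality (the curve plateau); (3) afterwards, walkers follow
#' general-population mortality scaled by `ambulatory_hazard_multiplier`
#' while non-walkers and ventilated patients add the constant excess hazard
#' `vent_excess_hazard` on top of background mortality as independent risks
#' `1 - (1 - p_bg) (1 - p_excess)`.
#'
#' @param km_os Overall-survival `km_curve`; must cover the evidence window.
#' @param life_table Background life table.
#' @param params A `pompe_params` object.
#' @param n_cycles Number of cycles; defaults to the full horizon.
#' @return Tibble `cycle`, `p_death_no_walk`, `p_death_walk`, `p_death_vent`.
#' @export
build_clinical_mortality <- function(km_os, life_table, params, n_cycles = NULL) {
  if (!inherits(km_os, "km_curve")) km_os <- km_curve(km_os)
  if (is.null(n_cycles)) n_cycles <- n_model_cycles(params)
  cycle_months <- params$cycle_years * 12
  window <- params$clinical_km_window_months
  plateau_end <- params$clinical_plateau_end_months
  if (max(km_os$time_months) < window) {
    stop("overall-survival curve must cover the first ", window, " months",
         call. = FALSE)
  }
  k <- 0:(n_cycles - 1)
  start_month <- k * cycle_months
  age <- floor(k * params$cycle_years)
  p_bg <- annual_prob_to_cycle(lifetable_annual_prob(life_table, age),
                               params$cycle_years)
  km_cycles <- sum(start_month < window)
  p_km <- km_interval_probs(km_os, cycle_months, n_cycles = km_cycles)

  in_km <- start_month < window
  in_plateau <- !in_km & start_month < plateau_end
  post <- !in_km & !in_plateau

  p_excess <- hazard_to_cycle_prob(params$vent_excess_hazard, params$cycle_years)
  p_no_walk <- p_walk <- p_vent <- numeric(n_cycles)
  p_no_walk[in_km] <- p_walk[in_km] <- p_vent[in_km] <- p_km
  p_no_walk[in_plateau] <- p_walk[in_plateau] <- p_vent[in_plateau] <- p_bg[in_plateau]
  p_walk[post] <- pmin(p_bg[post] * params$ambulatory_hazard_multiplier, 1)
  p_no_walk[post] <- p_vent[post] <- 1 - (1 - p_bg[post]) * (1 - p_excess)

  tibble::tibble(
    cycle = k,
    p_death_no_walk = p_no_walk,
    p_death_walk = p_walk,
    p_death_vent = p_vent
  )
}

#' Per-cycle ventilation-onset probabilities
#'
#' The ventilation-free-survival curve treats ventilation-or-death as the
#' event; subtracting the overall-survival death probability isolates
#' ventilation onset.  Digitization noise can make the overall curve drop
#' faster within a cycle, so the difference is floored at 0.
#'
#' @param km_vfs Ventilation-free-survival `km_curve`.
#' @param km_os Overall-survival `km_curve`.
#' @param cycle_months Cycle length in months.
#' @param n_cycles Number of cycles to tabulate (flat extension beyond the
#'   curves' support).
#' @return Numeric vector of unconditional per-cycle onset probabilities.
#' @export
build_ventilation_onset <- function(km_vfs, km_os, cycle_months, n_cycles) {
  p_event <- km_interval_probs(km_vfs, cycle_months, n_cycles = n_cycles)
  p_death <- km_interval_probs(km_os, cycle_months, n_cycles = n_cycles)
  pmax(p_event - p_death, 0)
}

n_model_cycles <- function(params, horizon_years = NULL) {
  horizon <- if (is.null(horizon_years)) params$horizon_years else horizon_years
  n <- round(horizon / params$cycle_years)
  if (n < 1) stop("horizon shorter than one cycle", call. = FALSE)
  n
}

#' Assemble the per-cycle transition schedule for one strategy
#'
#' Builds the sequence of 4x4 transition matrices over the states
#' unable-to-walk, able-to-walk, ventilator-dependent, death.  Within a
#' cycle, events are ordered death, then ventilation onset, then walking
#' acquisition, applied as nested conditionals so every row sums to 1
#' exactly.  Ventilation onset is taken from the KM decomposition as an
#' unconditional cycle probability and rescaled by survival so the
#' matrix entry reproduces it; it applies from the unable-to-walk state
#' (and, if `params$vent_onset_from_walk`, also from the able-to-walk
#' state).  In the screened arm ventilation does not occur and mortality is
#' general-population throughout; walkers can never lose ambulation; death
#' is absorbing.
#'
#' @param params A `pompe_params` object.
#' @param arm `"NBS"` or `"NoNBS"`.
#' @param bundle Input bundle with `life_table`, `km_os`, `km_vfs`.
#' @param n_cycles Number of cycles; defaults to the full horizon.
#' @return A `transition_schedule`: list with `arr` (n_cycles x 4 x 4
#'   array), `arm`, `cycle_years`, `n_cycles`.
#' @export
build_schedule <- function(params, arm = c("NBS", "NoNBS"), bundle,
                           n_cycles = NULL) {
  params <- validate_parameters(params)
  arm <- match.arg(arm)
  if (is.null(n_cycles)) n_cycles <- n_model_cycles(params)
  cycle_months <- params$cycle_years * 12

  if (arm == "NBS") {
    mort <- build_nbs_mortality(bundle$life_table, params, n_cycles)
    p_vent_onset <- rep(0, n_cycles)
    q_walk <- walking_transition_probs(params$nbs_walk_schedule,
                                       cycle_months, n_cycles)
  } else {
    mort <- build_clinical_mortality(bundle$km_os, bundle$life_table,
                                     params, n_cycles)
    p_vent_onset <- build_ventilation_onset(bundle$km_vfs, bundle$km_os,
                                            cycle_months, n_cycles)
    q_walk <- walking_transition_probs(params$clinical_walk_schedule,
                                       cycle_months, n_cycles)
  }

  arr <- array(0, dim = c(n_cycles, 4, 4),
               dimnames = list(NULL, pompe_states, pompe_states))
  for (k in seq_len(n_cycles)) {
    pd_nw <- mort$p_death_no_walk[k]
    pd_w <- mort$p_death_walk[k]
    pd_v <- mort$p_death_vent[k]
    # unconditional onset -> conditional on surviving the cycle
    pv <- if (pd_nw < 1) min(p_vent_onset[k] / (1 - pd_nw), 1) else 0
    qw <- q_walk[k]

    m <- matrix(0, 4, 4)
    m[1, 4] <- pd_nw
    m[1, 3] <- (1 - pd_nw) * pv
    m[1, 2] <- (1 - pd_nw) * (1 - pv) * qw
    m[1, 1] <- 1 - m[1, 2] - m[1, 3] - m[1, 4]
    if (isTRUE(params$vent_onset_from_walk)) {
      pv_w <- if (pd_w < 1) min(p_vent_onset[k] / (1 - pd_w), 1) else 0
      m[2, 4] <- pd_w
      m[2, 3] <- (1 - pd_w) * pv_w
      m[2, 2] <- 1 - m[2, 3] - m[2, 4]
    } else {
      m[2, 4] <- pd_w
      m[2, 2] <- 1 - pd_w
    }
    m[3, 4] <- pd_v
    m[3, 3] <- 1 - pd_v
    m[4, 4] <- 1
    if (any(m < -1e-15) || any(abs(rowSums(m) - 1) > 1e-12)) {
      stop("invalid transition matrix at cycle ", k - 1, call. = FALSE)
    }
    arr[k, , ] <- m
  }
  structure(list(arr = arr, arm = arm, cycle_years = params$cycle_years,
                 n_cycles = n_cycles),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat(sprintf("<transition_schedule> arm %s, %d cycles of %.2g y\n",
              x$arm, x$n_cycles, x$cycle_years))
  invisible(x)
}

#' Long-format view of a transition schedule
#'
#' @param x A `transition_schedule`.
#' @param ... Unused.
#' @return Tibble `cycle`, `from`, `to`, `probability`.
#' @method as_tibble transition_schedule
#' @export
as_tibble.transition_schedule <- function(x, ...) {
  grid <- expand.grid(cycle = 0:(x$n_cycles - 1), from = pompe_states,
                      to = pompe_states, stringsAsFactors = FALSE)
  grid$probability <- mapply(function(k, f, t) x$arr[k + 1, f, t],
                             grid$cycle, grid$from, grid$to)
  dplyr::arrange(tibble::as_tibble(grid), .data$cycle, .data$from, .data$to)
}
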