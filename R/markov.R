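#' Run the deterministic Markov cohort
#'
#' Propagates state-occupancy fractions through the per-cycle transition
#' matrices: `occupancy[k + 1] = occupancy[k] %*% M[k]`.  Row 0 of the
#' trace is the initial distribution; affected infants start entirely in
#' the unable-to-walk state.
#'
#' @param schedule A `transition_schedule`.
#' @param init Initial distribution over the four states (sums to 1);
#'   default all mass in unable-to-walk.
#' @param n_cycles Cycles to run; must not exceed the schedule length.
#' @return A `cohort_trace` tibble: `cycle`, `time_years`, then one
#'   occupancy column per state.
#' @export
run_cohort <- function(schedule, init = c(1, 0, 0, 0),
                       n_cycles = schedule$n_cycles) {
  stopifnot(inherits(schedule, "transition_schedule"))
  if (length(init) != 4 || any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    stop("initial distribution must be 4 non-negative values summing to 1",
         call. = FALSE)
  }
  if (n_cycles > schedule$n_cycles) {
    stop("schedule covers ", schedule$n_cycles, " cycles; ", n_cycles,
         " requested", call. = FALSE)
  }
  occ <- matrix(0, nrow = n_cycles + 1, ncol = 4,
                dimnames = list(NULL, pompe_states))
  occ[1, ] <- init
  for (k in seq_len(n_cycles)) {
    occ[k + 1, ] <- occ[k, ] %*% schedule$arr[k, , ]
  }
  new_trace(occ, schedule$cycle_years)
}

new_trace <- function(occ, cycle_years, se = NULL) {
  colnames(occ) <- pompe_states
  out <- tibble::as_tibble(as.data.frame(occ))
  out <- tibble::add_column(out,
    cycle = 0:(nrow(occ) - 1),
    time_years = (0:(nrow(occ) - 1)) * cycle_years,
    .before = 1
  )
  if (!is.null(se)) {
    colnames(se) <- paste0("se_", pompe_states)
    out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(se)))
  }
  structure(out, class = c("cohort_trace", class(out)),
            cycle_years = cycle_years)
}

trace_matrix <- function(trace) {
  as.matrix(trace[, pompe_states])
}

#' Microsimulation oracle for the cohort engine
#'
#' Simulates `n_individuals` one transition draw at a time through the same
#' schedule and returns the empirical occupancy trace with per-cell
#' binomial standard errors.  Used to cross-check [run_cohort()]; it shares
#' no arithmetic with it beyond the transition matrices themselves.
#'
#' @param schedule A `transition_schedule`.
#' @param init Initial distribution (individuals are allocated by
#'   multinomial draw).
#' @param n_individuals Number of simulated individuals.
#' @param seed RNG seed (restored afterwards).
#' @param n_cycles Cycles to run.
#' @return A `cohort_trace` tibble with additional `se_*` columns.
#' @export
microsim_oracle <- function(schedule, init = c(1, 0, 0, 0),
                            n_individuals = 1e5, seed = 1L,
                            n_cycles = schedule$n_cycles) {
  stopifnot(inherits(schedule, "transition_schedule"), n_individuals > 0)
  withr::with_seed(as.integer(seed), {
    state <- sample.int(4, n_individuals, replace = TRUE, prob = init)
    occ <- matrix(0, nrow = n_cycles + 1, ncol = 4)
    occ[1, ] <- tabulate(state, nbins = 4) / n_individuals
    for (k in seq_len(n_cycles)) {
      state_at_start <- state # one draw per individual per cycle
      for (s in 1:3) {
        idx <- which(state_at_start == s)
        if (length(idx) > 0) {
          state[idx] <- sample.int(4, length(idx), replace = TRUE,
                                   prob = schedule$arr[k, s, ])
        }
      }
      occ[k + 1, ] <- tabulate(state, nbins = 4) / n_individuals
    }
    se <- sqrt(occ * (1 - occ) / n_individuals)
    new_trace(occ, schedule$cycle_years, se = se)
  })
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %d cycles (%.1f years)\n",
              nrow(x) - 1, max(x$time_years)))
  NextMethod()
}

#' Plot a cohort trace
#'
#' Stacked-area state-occupancy plot over time.
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("time_years", pompe_states)],
                              -"time_years",
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = rev(pompe_states))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_years, .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age (years)", y = "State occupancy", fill = "State") +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan--Meier curve
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time_months, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival") +
    ggplot2::theme_minimal()
}
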