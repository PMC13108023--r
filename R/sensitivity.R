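#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the full pipeline twice per parameter -- once at its low and once
#' at its high bound, everything else held at base -- and records the
#' resulting ICER per QALY.  Rows are ordered by descending span
#' `|icer_high - icer_low|`; runs where one strategy dominates are kept
#' with an `NA` ICER and the dominance flag, not dropped.
#'
#' @param params Base `pompe_params`.
#' @param bundle Input bundle.
#' @param ranges Tibble `parameter`, `low`, `high` (default
#'   [default_ranges()]).
#' @param horizon_years Optional restricted horizon.
#' @return A `pompe_dsa` tibble: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `dominance_low`, `dominance_high`, `span`, with the
#'   base-case ICER attached as attribute `base_icer`.
#' @export
one_way_dsa <- function(params = cea_parameters(), bundle = synthetic_bundle(),
                        ranges = default_ranges(params), horizon_years = NULL) {
  params <- validate_parameters(params)
  base <- run_cea(params, bundle, horizon_years)
  base_icer <- base$increments$icer_qaly

  run_at <- function(parameter, value) {
    p <- params
    p[[parameter]] <- value
    res <- run_cea(validate_parameters(p), bundle, horizon_years)
    list(icer = res$increments$icer_qaly, dominance = res$increments$dominance)
  }
  rows <- purrr::pmap(ranges[c("parameter", "low", "high")],
    function(parameter, low, high) {
      lo <- run_at(parameter, low)
      hi <- run_at(parameter, high)
      tibble::tibble(
        parameter = parameter, low = low, high = high,
        icer_low = lo$icer, icer_high = hi$icer,
        dominance_low = lo$dominance, dominance_high = hi$dominance,
        span = abs(hi$icer - lo$icer)
      )
    })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$span), .data$parameter)
  structure(out, class = c("pompe_dsa", class(out)), base_icer = base_icer)
}

#' Restricted-horizon scenario analysis
#'
#' Reruns the analysis with rewards and transitions truncated at the given
#' horizon; cohort members still alive at the boundary simply stop
#' accruing (they are not forced to death).
#'
#' @param params A `pompe_params` object.
#' @param bundle Input bundle.
#' @param horizon_years Scenario horizon in years (e.g. 20).
#' @return A `pompe_cea` object.
#' @export
scenario_horizon <- function(params = cea_parameters(),
                             bundle = synthetic_bundle(), horizon_years = 20) {
  run_cea(params, bundle, horizon_years = horizon_years)
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' Horizontal bars from the low-bound to the high-bound ICER for each
#' parameter, ordered by span, with the base-case ICER as a reference
#' line.  Dominated/dominant runs (no finite ICER) are omitted from the
#' bars.
#'
#' @param object A `pompe_dsa` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pompe_dsa
#' @export
autoplot.pompe_dsa <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat <- dat[is.finite(dat$icer_low) & is.finite(dat$icer_high), ]
  dat$parameter <- factor(dat$parameter, levels = rev(dat$parameter))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = attr(object, "base_icer"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (JPY per QALY)", y = NULL) +
    ggplot2::theme_minimal()
}
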