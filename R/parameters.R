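#' Model health states
#'
#' State labels used throughout the package, in transition-matrix order:
#' unable to walk, able to walk independently, ventilator-dependent, death.
#'
#' @format Character vector of length 4.
#' @export
pompe_states <- c("no_walk", "walk", "vent", "dead")

# fields validated as probabilities / proportions in [0, 1]
.prob_fields <- c(
  "prevalence", "sensitivity", "specificity", "retest_rate",
  "confirm_proportion", "utility_no_walk", "utility_walk", "utility_vent",
  "utility_genpop"
)

# fields validated as non-negative
.nonneg_fields <- c(
  "cost_screen", "cost_retest", "cost_genetic", "cost_mgmt_month",
  "cost_vent_month", "vial_price", "vial_mg", "dose_mg_per_kg",
  "infusion_interval_weeks", "discount_rate", "treatment_delay_months",
  "vent_excess_hazard", "clinical_km_window_months",
  "clinical_plateau_end_months", "ambulatory_hazard_multiplier"
)

.schedule_fields <- c("nbs_walk_schedule", "clinical_walk_schedule")

#' Base-case parameter set
#'
#' Construct the full model parameter set for the Japanese newborn-screening
#' analysis of infantile-onset Pompe disease (IOPD).  Defaults are the
#' base-case inputs: a 727,288-newborn annual birth cohort, IOPD prevalence
#' of one in 297,387, a 3,000 JPY dried-blood-spot screening test with a
#' 0.11% recall rate, avalglucosidase alfa priced at 196,940 JPY per 100 mg
#' vial with weight-based dosing, health-state utilities 0.55 / 0.75 / 0.23
#' (unable to walk / able to walk / ventilator-dependent) against a 0.95
#' general-population anchor, a 2% annual discount rate, 6-month Markov
#' cycles and a lifetime horizon closing at age 110.
#'
#' Walking-acquisition schedules are cumulative proportions of surviving
#' patients walking by age: under screening all patients walk by 24 months
#' (80% by 18 months); under clinical identification 40% walk, spread
#' evenly between 12 and 30 months.
#'
#' @param ... Named overrides of any default field, e.g.
#'   `cea_parameters(discount_rate = 0)`.
#' @return A validated `pompe_params` object (a named list).
#' @examples
#' p <- cea_parameters()
#' p$births * p$prevalence # expected IOPD cases
#' @export
cea_parameters <- function(...) {
  overrides <- list(...)
  params <- default_parameters()
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(overrides)) {
    value <- overrides[[nm]]
    if (nm %in% .schedule_fields) value <- as_walk_schedule(value, nm)
    params[[nm]] <- value
  }
  validate_parameters(params)
}

default_parameters <- function() {
  structure(list(
    births = 727288,
    prevalence = 1 / 297387,
    sensitivity = 1,
    specificity = 0.9989,
    retest_rate = 0.0011,
    confirm_proportion = 0.487,
    cost_screen = 3000,
    cost_retest = 3000,
    cost_genetic = 38800,
    cost_mgmt_month = 347301,
    cost_vent_month = 102800,
    vial_price = 196940,
    vial_mg = 100,
    dose_mg_per_kg = 40,
    infusion_interval_weeks = 2,
    utility_no_walk = 0.55,
    utility_walk = 0.75,
    utility_vent = 0.23,
    utility_genpop = 0.95,
    discount_rate = 0.02,
    cycle_years = 0.5,
    horizon_years = 110,
    treatment_delay_months = 1.5,
    nbs_walk_schedule = tibble::tibble(
      age_months = c(18, 24), cum_prop = c(0.8, 1.0)
    ),
    clinical_walk_schedule = tibble::tibble(
      age_months = c(12, 18, 24, 30), cum_prop = c(0.1, 0.2, 0.3, 0.4)
    ),
    vent_excess_hazard = 0.0257,
    clinical_km_window_months = 48,
    clinical_plateau_end_months = 138,
    ambulatory_hazard_multiplier = 1,
    half_cycle = "none",
    vent_onset_from_walk = FALSE
  ), class = "pompe_params")
}

as_walk_schedule <- function(x, field) {
  if (is.data.frame(x)) {
    if (!all(c("age_months", "cum_prop") %in% names(x))) {
      stop(field, ": walking schedule needs columns age_months and cum_prop",
           call. = FALSE)
    }
    return(tibble::as_tibble(x[c("age_months", "cum_prop")]))
  }
  if (is.list(x) && all(c("age_months", "cum_prop") %in% names(x))) {
    # column-wise form (e.g. YAML serialisation of a data frame)
    return(tibble::tibble(age_months = as.numeric(unlist(x$age_months)),
                          cum_prop = as.numeric(unlist(x$cum_prop))))
  }
  # list-of-pairs form from configuration documents
  tibble::tibble(
    age_months = purrr::map_dbl(x, ~ as.numeric(.x[[1]])),
    cum_prop = purrr::map_dbl(x, ~ as.numeric(.x[[2]]))
  )
}

#' Validate a parameter set
#'
#' Checks every invariant the model relies on: probabilities and utilities
#' in \[0, 1\], non-negative costs and hazards, a positive cycle length, a
#' horizon of at least one cycle, and walking schedules whose cumulative
#' proportions are non-decreasing and at most 1.
#'
#' @param params A named list of model parameters.
#' @return The validated `pompe_params` object, invisibly classed.
#' @export
validate_parameters <- function(params) {
  missing <- setdiff(names(default_parameters()), names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in .prob_fields) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("parameter '%s' must be a probability in [0, 1], got %s",
                   nm, format(v)), call. = FALSE)
    }
  }
  for (nm in .nonneg_fields) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop(sprintf("parameter '%s' must be non-negative, got %s",
                   nm, format(v)), call. = FALSE)
    }
  }
  if (!is.numeric(params$births) || params$births <= 0) {
    stop("parameter 'births' must be positive", call. = FALSE)
  }
  if (params$cycle_years <= 0) {
    stop("parameter 'cycle_years' must be positive", call. = FALSE)
  }
  if (params$horizon_years < params$cycle_years) {
    stop("parameter 'horizon_years' must cover at least one cycle", call. = FALSE)
  }
  if (!params$half_cycle %in% c("none", "half-cycle")) {
    stop("parameter 'half_cycle' must be \"none\" or \"half-cycle\"", call. = FALSE)
  }
  for (nm in .schedule_fields) {
    sched <- params[[nm]]
    if (!is.data.frame(sched)) {
      stop(sprintf("parameter '%s' must be a data frame", nm), call. = FALSE)
    }
    if (nrow(sched) > 0) {
      if (is.unsorted(sched$age_months, strictly = TRUE)) {
        stop(sprintf("parameter '%s': ages must be strictly increasing", nm),
             call. = FALSE)
      }
      if (is.unsorted(sched$cum_prop) || any(sched$cum_prop < 0) ||
          any(sched$cum_prop > 1)) {
        stop(sprintf(
          "parameter '%s': cumulative proportions must be non-decreasing in [0, 1]",
          nm), call. = FALSE)
      }
    }
  }
  structure(params, class = "pompe_params")
}

#' Load parameters from a configuration document
#'
#' Reads a YAML or JSON configuration and merges it over the base case.
#' Every field absent from the document keeps its base-case default;
#' present fields are validated.  Walking schedules may be given as a list
#' of `[age_months, cum_prop]` pairs or as records with those names.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a named list of
#'   overrides (useful for programmatic calls); `NULL` gives the base case.
#' @param overrides Named list applied after the document, e.g. from
#'   command-line `--set key=value` flags.
#' @return A validated `pompe_params` object.
#' @export
load_parameters <- function(config = NULL, overrides = list()) {
  doc <- list()
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("configuration file not found: ", config, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(config))
    doc <- switch(ext,
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      yaml = ,
      yml = yaml::read_yaml(config),
      stop("unsupported configuration format: .", ext, call. = FALSE)
    )
  } else if (is.list(config)) {
    doc <- config
  } else if (!is.null(config)) {
    stop("config must be a file path, a named list, or NULL", call. = FALSE)
  }
  doc[names(overrides)] <- overrides
  params <- default_parameters()
  unknown <- setdiff(names(doc), names(params))
  if (length(unknown) > 0) {
    stop("unknown parameter(s) in configuration: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(doc)) {
    value <- doc[[nm]]
    if (nm %in% .schedule_fields) value <- as_walk_schedule(value, nm)
    params[[nm]] <- value
  }
  validate_parameters(params)
}

#' Write parameters to a configuration document
#'
#' Serialises a parameter set so that `load_parameters()` on the written
#' file reproduces it exactly (full double precision for JSON).
#'
#' @param params A `pompe_params` object.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  doc <- unclass(params)
  for (nm in .schedule_fields) {
    doc[[nm]] <- as.data.frame(doc[[nm]])
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 15)
  } else {
    stop("unsupported configuration format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @export
print.pompe_params <- function(x, ...) {
  cat("<pompe_params> base-case model inputs\n")
  cat(sprintf("  cohort: %s births, prevalence 1 in %s\n",
              format(x$births, big.mark = ","),
              format(round(1 / x$prevalence), big.mark = ",")))
  cat(sprintf("  cycle %.1f y, horizon %.0f y, discount %.1f%%/y\n",
              x$cycle_years, x$horizon_years, 100 * x$discount_rate))
  cat(sprintf("  drug: %s JPY per %g mg vial, %g mg/kg every %g weeks\n",
              format(x$vial_price, big.mark = ","), x$vial_mg,
              x$dose_mg_per_kg, x$infusion_interval_weeks))
  invisible(x)
}

#' @method tidy pompe_params
#' @export
tidy.pompe_params <- function(x, ...) {
  scalar <- x[!names(x) %in% .schedule_fields]
  tibble::tibble(
    parameter = names(scalar),
    value = purrr::map(scalar, identity)
  )
}

#' Default one-way sensitivity ranges
#'
#' One row per parameter varied in the deterministic sensitivity analysis.
#' Published plausible ranges are used where they exist (screening cost
#' 0--5,000; genetic test 31,040--46,560; management 277,841--416,761 and
#' ventilation 82,240--123,360 JPY per month; recall 0.085--0.128%;
#' confirmatory testing 39.0--58.5%; utilities 0.40--0.70, 0.60--0.90 and
#' 0.08--0.38; drug price +/-20%); prevalence is varied upward only, to one
#' in 100,000; remaining parameters get +/-20% of their base value.
#'
#' @param params A `pompe_params` object supplying base values.
#' @return A tibble with columns `parameter`, `low`, `high`, `source`
#'   (`"table"` for published ranges, `"pm20"` for the +/-20% default).
#' @export
default_ranges <- function(params = cea_parameters()) {
  params <- validate_parameters(params)
  pm20 <- function(base) c(0.8 * base, 1.2 * base)
  rows <- list(
    list("prevalence", params$prevalence, 1 / 100000, "table"),
    list("retest_rate", 0.00085, 0.00128, "table"),
    list("confirm_proportion", 0.390, 0.585, "table"),
    list("cost_screen", 0, 5000, "table"),
    list("cost_genetic", 31040, 46560, "table"),
    list("cost_mgmt_month", 277841, 416761, "table"),
    list("cost_vent_month", 82240, 123360, "table"),
    list("vial_price", pm20(params$vial_price)[1], pm20(params$vial_price)[2], "table"),
    list("utility_no_walk", 0.40, 0.70, "table"),
    list("utility_walk", 0.60, 0.90, "table"),
    list("utility_vent", 0.08, 0.38, "table"),
    list("discount_rate", pm20(params$discount_rate)[1], pm20(params$discount_rate)[2], "pm20"),
    list("vent_excess_hazard", pm20(params$vent_excess_hazard)[1], pm20(params$vent_excess_hazard)[2], "pm20")
  )
  out <- tibble::tibble(
    parameter = purrr::map_chr(rows, 1),
    low = purrr::map_dbl(rows, 2),
    high = purrr::map_dbl(rows, 3),
    source = purrr::map_chr(rows, 4)
  )
  base <- purrr::map_dbl(out$parameter, ~ params[[.x]])
  bad <- out$low > base + 1e-12 | out$high < base - 1e-12
  if (any(bad)) {
    stop("sensitivity range excludes the base value for: ",
         paste(out$parameter[bad], collapse = ", "), call. = FALSE)
  }
  out
}
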