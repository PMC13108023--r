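# shared fixtures, built once per test run

base_params <- cea_parameters()
base_bundle <- synthetic_bundle()

# flat life table: constant annual death probability at every age
flat_lifetable <- function(p_annual, max_age = 120) {
  tibble::tibble(age_years = 0:max_age, p_death_annual = p_annual)
}

# constant QOL norms (adjustment factor 1 at every age)
flat_norms <- function(value = 0.95, max_age = 120) {
  tibble::tibble(age_years = 0:max_age, norm = value)
}

# bundle with fully controllable flat components
flat_bundle <- function(p_annual = 0, norm = 0.95, weight_kg = 10,
                        km = make_km_curves()) {
  structure(list(
    life_table = flat_lifetable(p_annual),
    km_os = km$os,
    km_vfs = km$vfs,
    qol_norms = flat_norms(norm),
    weight = tibble::tibble(age_years = 0:120, weight_kg = weight_kg),
    manifest = list()
  ), class = "synthetic_bundle")
}

# randomized but valid inputs for property-style tests
random_bundle <- function(seed) {
  withr::with_seed(seed, {
    p <- runif(1, 0, 0.3)
    eh <- runif(1, 0.015, 0.08)
    os <- runif(1, 0.3, 0.95)
    vfs <- runif(1, 0.05, 1) * os
    structure(list(
      life_table = flat_lifetable(p),
      km_os = make_km_curves(eh, os, vfs)$os,
      km_vfs = make_km_curves(eh, os, vfs)$vfs,
      qol_norms = make_qol_norms(),
      weight = make_weight_table(),
      manifest = list()
    ), class = "synthetic_bundle")
  })
}

random_params <- function(seed) {
  withr::with_seed(seed, {
    cea_parameters(
      vent_excess_hazard = runif(1, 0, 0.3),
      ambulatory_hazard_multiplier = runif(1, 0.5, 1.5),
      horizon_years = 60,
      clinical_walk_schedule = tibble::tibble(
        age_months = c(12, 24, 36),
        cum_prop = sort(runif(3, 0, 1))
      )
    )
  })
}
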