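test_that("probability and hazard conversions match closed forms", {
  expect_equal(annual_prob_to_cycle(0.02, 0.5), 0.0100505063388334, tolerance = 1e-12)
  expect_equal(annual_prob_to_cycle(0, 0.5), 0)
  expect_equal(annual_prob_to_cycle(1, 0.5), 1)
  expect_equal(hazard_to_cycle_prob(0.0257, 0.5), 0.0127677912542076, tolerance = 1e-12)
  expect_equal(hazard_to_cycle_prob(0.0257, 1.0), 0.0253725660149042, tolerance = 1e-12)
  expect_equal(hazard_to_cycle_prob(0, 0.5), 0)
})

test_that("KM interval probabilities follow conditional-survival definition", {
  c1 <- km_curve(tibble::tibble(time_months = c(0, 6, 12), survival = c(1, 0.8, 0.8)))
  expect_equal(km_interval_probs(c1, 6), c(0.2, 0))
  c2 <- km_curve(tibble::tibble(time_months = c(0, 3, 6), survival = c(1, 0.5, 0.25)))
  expect_equal(km_interval_probs(c2, 6), 0.75)
  flat <- km_curve(tibble::tibble(time_months = c(0, 60), survival = c(1, 1)))
  expect_equal(km_interval_probs(flat, 6), rep(0, 10))
  # exhausted risk set yields zero, not NaN
  dead <- km_curve(tibble::tibble(time_months = c(0, 6), survival = c(1, 0)))
  expect_equal(km_interval_probs(dead, 6, n_cycles = 3), c(1, 0, 0))
})

test_that("KM curves are validated and digitization noise is repairable", {
  expect_error(km_curve(tibble::tibble(time_months = c(1, 2), survival = c(1, 0.5))),
               "start")
  noisy <- tibble::tibble(time_months = c(0, 3, 6, 9),
                          survival = c(1, 0.7, 0.72, 0.5))
  expect_error(km_curve(noisy), "non-increasing")
  repaired <- suppressMessages(repair_km_curve(noisy))
  expect_message(repair_km_curve(noisy), "monotone projection")
  expect_equal(repaired$survival, c(1, 0.7, 0.7, 0.5))
})

test_that("interval probabilities recompose the survival curve", {
  for (curve in list(base_bundle$km_os, base_bundle$km_vfs,
                     random_bundle(11)$km_os, random_bundle(12)$km_os)) {
    probs <- km_interval_probs(curve, 6)
    recomposed <- cumprod(1 - probs)
    boundaries <- 6 * seq_along(probs)
    idx <- match(boundaries, curve$time_months)
    expect_equal(recomposed, curve$survival[idx], tolerance = 1e-12)
  }
})

test_that("walking schedules convert to conditional per-cycle probabilities", {
  # screened arm: 80% walk by 18 months, everyone by 24
  q_nbs <- walking_transition_probs(base_params$nbs_walk_schedule, 6, 6)
  expect_equal(q_nbs, c(0, 0, 0.8, 1, 0, 0))
  # clinical arm: 40% spread evenly 12-30 months
  q_cl <- walking_transition_probs(base_params$clinical_walk_schedule, 6, 6)
  expect_equal(q_cl, c(0, 0.1, 0.1 / 0.9, 0.1 / 0.8, 0.1 / 0.7, 0),
               tolerance = 1e-12)
  expect_equal(walking_transition_probs(NULL, 6, 4), rep(0, 4))
  expect_equal(walking_transition_probs(tibble::tibble(age_months = numeric(),
                                                       cum_prop = numeric()), 6, 4),
               rep(0, 4))
})

test_that("clinical mortality splices KM window, plateau and excess hazard", {
  p <- cea_parameters()
  # within the evidence window the KM probabilities pass through unchanged
  mort <- build_clinical_mortality(base_bundle$km_os, base_bundle$life_table, p)
  km <- km_interval_probs(base_bundle$km_os, 6, n_cycles = 8)
  expect_equal(mort$p_death_no_walk[1:8], km)
  expect_equal(mort$p_death_walk[1:8], km)
  expect_equal(mort$p_death_vent[1:8], km)
  # plateau phase: background mortality, identical across alive states
  flat <- flat_lifetable(0.001)
  mort2 <- build_clinical_mortality(base_bundle$km_os, flat, p)
  plateau_cycles <- 9:23 # months 48-138
  expect_equal(mort2$p_death_walk[plateau_cycles],
               rep(0.000500125062539047, length(plateau_cycles)), tolerance = 1e-12)
  # post-plateau: excess hazard only when background is zero
  mort3 <- build_clinical_mortality(base_bundle$km_os, flat_lifetable(0), p)
  post <- mort3$cycle * 6 >= 138
  expect_equal(unique(mort3$p_death_vent[post]), 0.0127677912542076, tolerance = 1e-12)
  expect_equal(unique(mort3$p_death_no_walk[post]), 0.0127677912542076, tolerance = 1e-12)
  expect_equal(unique(mort3$p_death_walk[post]), 0)
  short <- km_curve(tibble::tibble(time_months = c(0, 12), survival = c(1, 0.9)))
  expect_error(build_clinical_mortality(short, flat, p), "48")
})

test_that("screened-arm mortality tracks the life table age index", {
  p <- cea_parameters()
  m <- build_nbs_mortality(flat_lifetable(0.001), p, n_cycles = 10)
  expect_equal(m$p_death_walk, rep(0.000500125062539047, 10), tolerance = 1e-12)
  expect_true(all(m$p_vent_onset == 0))
  expect_equal(build_nbs_mortality(flat_lifetable(0), p, 10)$p_death_no_walk,
               rep(0, 10))
  varying <- tibble::tibble(age_years = 0:120, p_death_annual = (0:120) / 240)
  mv <- build_nbs_mortality(varying, p, n_cycles = 8)
  expect_equal(mv$p_death_walk,
               annual_prob_to_cycle(floor((0:7) * 0.5) / 240, 0.5))
})

test_that("ventilation onset is the composite-minus-death decomposition, floored", {
  vfs <- km_curve(tibble::tibble(time_months = c(0, 6), survival = c(1, 0.6)))
  os <- km_curve(tibble::tibble(time_months = c(0, 6), survival = c(1, 0.8)))
  expect_equal(build_ventilation_onset(vfs, os, 6, 1), 0.2)
  expect_equal(build_ventilation_onset(os, os, 6, 4), rep(0, 4))
  # digitization noise: OS dropping faster than VFS floors at zero
  expect_equal(build_ventilation_onset(os, vfs, 6, 1), 0)
})

test_that("assembled schedules are valid stochastic matrices", {
  for (seed in 1:6) {
    params <- random_params(seed)
    bundle <- random_bundle(seed + 100)
    for (arm in c("NBS", "NoNBS")) {
      sched <- build_schedule(params, arm, bundle)
      rs <- apply(sched$arr, 1, function(m) rowSums(matrix(m, 4, 4)))
      expect_true(all(abs(rs - 1) < 1e-12))
      expect_true(all(sched$arr >= 0))
      # death absorbing
      expect_true(all(sched$arr[, 4, 4] == 1))
    }
  }
})

test_that("screened-arm schedules never enter the ventilator state", {
  sched <- build_schedule(base_params, "NBS", base_bundle)
  off_diag <- sched$arr[, c(1, 2, 4), 3]
  expect_true(all(off_diag == 0))
})

test_that("zero hazards leave only walking transitions", {
  p <- cea_parameters(vent_excess_hazard = 0)
  b <- flat_bundle(p_annual = 0, km = make_km_curves(0, 1, 1))
  sched <- build_schedule(p, "NoNBS", b, n_cycles = 20)
  for (k in 1:20) {
    m <- sched$arr[k, , ]
    expect_equal(unname(m[1, 4]), 0)
    expect_equal(unname(m[2, ]), c(0, 1, 0, 0))
    expect_equal(unname(m[3, ]), c(0, 0, 1, 0))
  }
  # walking mass moves exactly per the conditional schedule
  q <- walking_transition_probs(p$clinical_walk_schedule, 6, 20)
  expect_equal(sched$arr[, 1, 2], q)
})

test_that("after the plateau ends, treated walkers revert to background mortality", {
  p <- cea_parameters(vent_excess_hazard = 0, ambulatory_hazard_multiplier = 1)
  clin <- build_clinical_mortality(base_bundle$km_os, base_bundle$life_table, p)
  nbs <- build_nbs_mortality(base_bundle$life_table, p)
  post <- clin$cycle * 6 >= 138
  expect_equal(clin$p_death_walk[post], nbs$p_death_walk[post], tolerance = 1e-15)
  expect_equal(clin$p_death_no_walk[post], nbs$p_death_no_walk[post], tolerance = 1e-15)
})

test_that("long-format schedule export preserves probabilities", {
  sched <- build_schedule(base_params, "NoNBS", base_bundle, n_cycles = 4)
  long <- as_tibble(sched)
  expect_equal(nrow(long), 4 * 16)
  expect_equal(
    long$probability[long$cycle == 2 & long$from == "no_walk" & long$to == "dead"],
    sched$arr[3, "no_walk", "dead"]
  )
  sums <- dplyr::summarise(dplyr::group_by(long, cycle, from),
                           s = sum(probability))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})
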