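test_that("discount factors follow (1 + r)^-t", {
  expect_equal(discount_factor(0.02, 0), 1)
  expect_equal(discount_factor(0.02, 1), 0.980392156862745, tolerance = 1e-12)
  expect_equal(discount_factor(0, 50), 1)
  expect_equal(discount_factor(0.02, 2), 1 / 1.02^2)
})

test_that("utilities are age-adjusted against the 16-19-year norm band", {
  norms <- make_qol_norms(0.95, 0.02)
  expect_equal(utility_at_age(0.75, 17, norms), 0.75)
  # decade decline: norm(85) = 0.95 - 7 * 0.02 = 0.81
  expect_equal(utility_at_age(0.75, 85, norms), 0.75 * 0.81 / 0.95)
  # custom table matching the documented example
  tab <- tibble::tibble(age_years = c(16:19, 85), norm = c(rep(0.95, 4), 0.85))
  expect_equal(utility_at_age(0.75, 85, tab), 0.75 * 0.85 / 0.95,
               tolerance = 1e-12)
  # ages 90+ clamp to the 80-89 band
  expect_equal(utility_at_age(0.95, 95, norms), utility_at_age(0.95, 85, norms))
  no_ref <- tibble::tibble(age_years = 30:40, norm = 0.9)
  expect_error(utility_at_age(0.75, 35, no_ref), "reference")
})

test_that("drug costs use whole-vial weight-based dosing", {
  w60 <- tibble::tibble(age_years = 0:100, weight_kg = 60)
  p20 <- cea_parameters(dose_mg_per_kg = 20)
  infusions <- (365.25 / 7) * 0.5 / 2
  expect_equal(drug_cost_per_cycle(30, w60, p20),
               ceiling(60 * 20 / 100) * 196940 * infusions)
  expect_equal(ceiling(60 * 20 / 100), 12) # 2,363,280 JPY per infusion
  w5 <- tibble::tibble(age_years = 0:100, weight_kg = 5)
  p40 <- cea_parameters(dose_mg_per_kg = 40)
  expect_equal(drug_cost_per_cycle(0, w5, p40), 2 * 196940 * infusions)
  free <- cea_parameters(vial_price = 0)
  expect_equal(drug_cost_per_cycle(0, w5, free), 0)
})

test_that("discounted life-years match the geometric closed form", {
  # constant 0.1 per-cycle death via a flat life table (1 - 0.81^0.5 = 0.1)
  p <- cea_parameters(discount_rate = 0, horizon_years = 100,
                      utility_no_walk = 1, utility_walk = 1, utility_vent = 1,
                      nbs_walk_schedule = tibble::tibble(age_months = numeric(),
                                                        cum_prop = numeric()))
  b <- flat_bundle(p_annual = 0.19, norm = 0.95)
  sched <- build_schedule(p, "NBS", b)
  out <- accrue(run_cohort(sched), p, b, "NBS")
  expect_equal(out$ly, 0.5 * sum(0.9^(0:199)), tolerance = 1e-9)
  expect_equal(out$ly, 5, tolerance = 1e-8)
})

test_that("QALYs equal life-years when every utility is 1", {
  p <- cea_parameters(utility_no_walk = 1, utility_walk = 1, utility_vent = 1)
  b <- flat_bundle(p_annual = 0.02, norm = 0.95) # flat norms: factor 1
  for (arm in c("NBS", "NoNBS")) {
    sched <- build_schedule(p, arm, b)
    out <- accrue(run_cohort(sched), p, b, arm)
    expect_equal(out$qaly, out$ly, tolerance = 1e-12)
  }
})

test_that("extreme discounting leaves only the first cycle's reward", {
  p <- cea_parameters(discount_rate = 1e30)
  b <- flat_bundle(p_annual = 0.02)
  sched <- build_schedule(p, "NBS", b)
  out <- accrue(run_cohort(sched), p, b, "NBS")
  expect_equal(out$ly, p$cycle_years) # cycle 0 undiscounted, rest ~0
})

test_that("discounting never increases any accrued component", {
  b <- base_bundle
  p0 <- cea_parameters(discount_rate = 0)
  p2 <- cea_parameters(discount_rate = 0.02)
  for (arm in c("NBS", "NoNBS")) {
    s0 <- build_schedule(p0, arm, b)
    t0 <- run_cohort(s0)
    o0 <- accrue(t0, p0, b, arm)
    o2 <- accrue(t0, p2, b, arm)
    for (col in c("ly", "qaly", "cost_mgmt", "cost_vent", "cost_drug")) {
      expect_lte(o2[[col]], o0[[col]])
    }
  }
})

test_that("the comparator's first-cycle drug cost reflects the treatment delay", {
  p <- cea_parameters(discount_rate = 0, horizon_years = 0.5)
  b <- flat_bundle(p_annual = 0, weight_kg = 10, km = make_km_curves(0, 1, 1))
  sched_nbs <- build_schedule(p, "NBS", b, 1)
  sched_cl <- build_schedule(p, "NoNBS", b, 1)
  drug_nbs <- accrue(run_cohort(sched_nbs), p, b, "NBS")$cost_drug
  drug_cl <- accrue(run_cohort(sched_cl), p, b, "NoNBS")$cost_drug
  expect_equal(drug_cl / drug_nbs, (6 - 1.5) / 6)
})

test_that("per-infant mixing is the prevalence-weighted decomposition", {
  b <- base_bundle
  p <- cea_parameters()
  cs <- cascade(p, "NBS")
  sched <- build_schedule(p, "NBS", b)
  patient <- accrue(run_cohort(sched), p, b, "NBS")
  gp <- genpop_outcome(p, b)
  mix <- per_infant_mix(patient, gp, cs, p)
  prev <- p$prevalence
  expect_equal(mix$qaly, prev * patient$qaly + (1 - prev) * gp$qaly)
  expect_equal(mix$cost_screening,
               (cs$cost_initial_screen + cs$cost_retests) / p$births)
  # decomposition identity, to 1e-6 JPY
  expect_equal(mix$cost_total,
               mix$cost_screening + mix$cost_genetic + mix$cost_mgmt +
                 mix$cost_vent + mix$cost_drug, tolerance = 1e-12)
  # degenerate prevalences collapse to the pure components
  p0 <- cea_parameters(prevalence = 1e-12)
  mix0 <- per_infant_mix(patient, gp, cs, p0)
  expect_equal(mix0$qaly, gp$qaly, tolerance = 1e-9)
})

test_that("ICERs divide unrounded increments and flag dominance", {
  mk <- function(cost_nbs, q_nbs, cost_ref, q_ref) tibble::tibble(
    arm = c("NBS", "NoNBS"), ly = c(q_nbs, q_ref), qaly = c(q_nbs, q_ref),
    cost_total = c(cost_nbs, cost_ref)
  )
  expect_equal(icer(mk(100, 2, 0, 0))$icer_qaly, 50)
  dom <- icer(mk(50, 3, 100, 1))
  expect_equal(dom$dominance, "dominant")
  expect_true(is.na(dom$icer_qaly))
  dominated <- icer(mk(100, 1, 50, 3))
  expect_equal(dominated$dominance, "dominated")
  zero <- icer(mk(100, 1, 50, 1))
  expect_equal(zero$dominance, "zero-effect")
  expect_true(is.na(zero$icer_qaly))
})

test_that("identical arms differ only by the cascade cost", {
  p <- cea_parameters()
  b <- base_bundle
  sched <- build_schedule(p, "NBS", b)
  trace <- run_cohort(sched)
  patient <- accrue(trace, p, b, "NBS")
  patient_ref <- patient
  patient_ref$arm <- "NoNBS"
  gp <- genpop_outcome(p, b)
  per_infant <- dplyr::bind_rows(
    per_infant_mix(patient, gp, cascade(p, "NBS"), p),
    per_infant_mix(patient_ref, gp, cascade(p, "NoNBS"), p)
  )
  inc <- icer(per_infant)
  expect_equal(inc$inc_qaly, 0)
  expect_equal(inc$inc_ly, 0)
  expect_equal(inc$inc_cost, cascade(p, "NBS")$cost_total / p$births,
               tolerance = 1e-12)
  expect_equal(inc$dominance, "zero-effect")
})

test_that("full pipeline satisfies structural sanity and drug dominance", {
  res <- run_cea(base_params, base_bundle)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  # QALY <= LY for every strategy
  expect_true(all(td$total_qalys <= td$total_lys))
  # screening arm: longer life, more QALYs, higher cost
  expect_gt(res$increments$inc_qaly, 0)
  expect_gt(res$increments$inc_ly, 0)
  expect_gt(res$increments$inc_cost, 0)
  # drug cost is the dominant component in both strategies
  shares <- cea_cost_breakdown(res)
  top <- dplyr::slice_max(dplyr::group_by(shares, arm), share, n = 1)
  expect_equal(unique(top$component), "drug")
  expect_true(all(top$share > 0.5))
})

test_that("half-cycle correction shrinks accruals but preserves ordering", {
  p_hc <- cea_parameters(half_cycle = "half-cycle")
  res <- run_cea(base_params, base_bundle)
  res_hc <- run_cea(p_hc, base_bundle)
  # state membership can only fall over time here, so averaging mid-cycle
  # reduces LY slightly
  expect_lt(tidy(res_hc)$total_lys[1], tidy(res)$total_lys[1])
  expect_gt(res_hc$increments$icer_qaly, 0)
})
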