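test_that("the state vector covers organs, blood pools and lumen segments", {
  model <- build_model(ofx, healthy_cohort_individual())
  expect_length(model$state_names, 3 + 11 + 1 + 3 + 3)
  expect_true(all(c("venous_blood", "arterial_blood", "lung", "stomach_lumen",
                    "si1", "si3", "eliminated_renal", "fecal_loss") %in%
                    model$state_names))
})

test_that("zero dose produces an identically zero profile", {
  model <- build_model(ofx, healthy_cohort_individual())
  for (route in c("iv_infusion", "oral")) {
    prof <- simulate_profile(model, dose_scenario(route, 0, horizon_h = 12,
                                                  grid_dt = 0.5))
    expect_true(all(prof$conc_ug_ml == 0))
  }
})

test_that("mass balance closes within 0.1% for IV, oral and multiple dosing", {
  model <- build_model(ofx, healthy_cohort_individual())
  scens <- list(
    fast_iv(),
    fast_po(),
    dose_scenario("oral", 400, n_doses = 4, interval_h = 12, horizon_h = 60,
                  grid_dt = 0.25),
    dose_scenario("iv_infusion", 400, infusion_h = 1, n_doses = 3,
                  interval_h = 12, horizon_h = 48, grid_dt = 0.25)
  )
  for (sc in scens) {
    prof <- simulate_profile(model, sc, states = TRUE)
    mb <- mass_balance(prof)
    expect_lt(max(abs(mb$rel_error)), 0.001)
  }
})

test_that("with all clearances off the dose is fully retained or in transit", {
  inert <- drug_with(ofx, hepatic_clearance_l_h_kg = 0,
                     tubular_secretion_l_h = 0, gfr_fraction = 0)
  model <- build_model(inert, healthy_cohort_individual())
  prof <- simulate_profile(model, fast_po(), states = TRUE)
  st <- attr(prof, "states")
  last <- st[nrow(st), ]
  expect_equal(last$eliminated_renal + last$eliminated_hepatic, 0,
               tolerance = 1e-9)
  body_and_lumen <- sum(last[, setdiff(names(last), "time_h")])
  expect_equal(body_and_lumen, 200, tolerance = 0.001 * 200)
})

test_that("doubling the dose doubles Cmax and AUC within 0.5%", {
  model <- build_model(ofx, healthy_cohort_individual())
  for (route in c("iv_infusion", "oral")) {
    r1 <- run_nca(simulate_profile(model, dose_scenario(route, 200,
                                                        horizon_h = 24,
                                                        grid_dt = 0.1)),
                  200, route)
    r2 <- run_nca(simulate_profile(model, dose_scenario(route, 400,
                                                        horizon_h = 24,
                                                        grid_dt = 0.1)),
                  400, route)
    expect_equal(r2$Cmax / r1$Cmax, 2, tolerance = 0.005)
    expect_equal(r2$AUC_0_t / r1$AUC_0_t, 2, tolerance = 0.005)
  }
})

test_that("IV AUC to infinity equals dose over total clearance within 2%", {
  ind <- healthy_cohort_individual()
  model <- build_model(ofx, ind)
  res <- run_nca(simulate_profile(model, fast_iv(horizon = 96)), 200,
                 "iv_infusion")
  expect_equal(res$AUC_0_inf, 200 / clearance_terms(ofx, ind)$CL_total,
               tolerance = 0.02)
})

test_that("oral exposure never exceeds IV exposure at equal dose", {
  model <- build_model(ofx, healthy_cohort_individual())
  iv <- run_nca(simulate_profile(model, fast_iv(horizon = 96)), 200,
                "iv_infusion")
  po <- run_nca(simulate_profile(model, fast_po(horizon = 96)), 200, "oral")
  expect_lt(po$AUC_0_inf, iv$AUC_0_inf * (1 + 1e-6))
  expect_lt(po$AUC_0_t, iv$AUC_0_t * (1 + 1e-6))
})

test_that("collapsed model matches a one-compartment analytic solution", {
  ind <- healthy_cohort_individual()
  organs <- c("lung", renopbpk:::TISSUES)
  kp1 <- setNames(rep(1, length(organs)), organs)
  model <- build_model(ofx, ind, kp_override = kp1, flow_scale = 1000)
  sc <- dose_scenario("iv_infusion", 200, infusion_h = 1, horizon_h = 36,
                      grid_dt = 0.1)
  prof <- simulate_profile(model, sc)
  V <- sum(ind$organs[[1]]$volume_l)
  CL <- clearance_terms(ofx, ind)$CL_total
  k <- CL / V
  R0 <- 200 / 1
  analytic <- ifelse(prof$time_h <= 1,
                     R0 / CL * (1 - exp(-k * prof$time_h)),
                     R0 / CL * (1 - exp(-k * 1)) * exp(-k * (prof$time_h - 1)))
  idx <- prof$time_h >= 0.5
  expect_equal(prof$conc_ug_ml[idx], analytic[idx], tolerance = 0.01)
})

test_that("missing Kp entries are rejected naming the organ", {
  expect_error(build_model(ofx, healthy_cohort_individual(),
                           kp_override = c(lung = 1, liver = 2)),
               "missing organ")
})

test_that("degenerate ensembles collapse the VPC band to the mean", {
  spec <- population_spec(3, "healthy", age_cv = 0, weight_cv = 0,
                          height_cv = 0, female_fraction = 0, cv_volumes = 0,
                          cv_flows = 0, egfr_range = c(110, 110), seed = 2)
  pop <- sample_population(spec)
  profs <- simulate_population(ofx, pop, fast_po(), rtol = 1e-6, atol = 1e-8)
  bands <- vpc_bands(profs)
  expect_equal(bands$p5, bands$mean, tolerance = 1e-9)
  expect_equal(bands$p95, bands$mean, tolerance = 1e-9)
})

test_that("VPC bands nest pointwise for a variable ensemble", {
  pop <- sample_population(population_spec(12, "healthy", seed = 17))
  profs <- simulate_population(ofx, pop, fast_po(), rtol = 1e-6, atol = 1e-8)
  bands <- vpc_bands(profs)
  expect_true(all(bands$min <= bands$p5 + 1e-12))
  expect_true(all(bands$p5 <= bands$median + 1e-12))
  expect_true(all(bands$median <= bands$p95 + 1e-12))
  expect_true(all(bands$p95 <= bands$max + 1e-12))
  # determinism given the population
  profs2 <- simulate_population(ofx, pop, fast_po(), rtol = 1e-6, atol = 1e-8)
  expect_identical(profs, profs2)
})

test_that("scenario validation enforces dosing consistency", {
  expect_error(dose_scenario("oral", -10), "dose_mg")
  expect_error(dose_scenario("iv_infusion", 100, infusion_h = 0), "infusion")
  expect_error(dose_scenario("oral", 100, n_doses = 4, interval_h = 12,
                             horizon_h = 24), "horizon")
})
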