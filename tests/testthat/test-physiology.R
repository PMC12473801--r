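test_that("reference demographics reproduce the packaged table unscaled", {
  ind <- make_reference_individual()
  ref <- reference_physiology()
  org <- ind$organs[[1]]
  expect_equal(org$volume_l, ref$volume_l)
  expect_equal(org$flow_l_per_h, ref$flow_l_per_h)
  expect_equal(ind$egfr, 110)
  expect_equal(ind$ka_ap, 0.55)
})

test_that("BSA matches an independent DuBois computation to 1e-10", {
  w <- c(50, 71, 95)
  h <- c(150, 175, 190)
  independent <- exp(log(0.007184) + 0.425 * log(w) + 0.725 * log(h))
  expect_equal(bsa_dubois(w, h), independent, tolerance = 1e-10)
})

test_that("demographic validation errors name the offending field", {
  expect_error(make_reference_individual(age = 10), "age")
  expect_error(make_reference_individual(weight = 200), "weight")
  expect_error(make_reference_individual(height = 100), "height")
})

test_that("healthy cohort individual carries its requested weight and sane GFR", {
  ind <- healthy_cohort_individual()
  expect_equal(ind$weight, 71)
  expect_gt(ind$gfr_abs_l_h, 5)
  expect_lt(ind$gfr_abs_l_h, 10)
})

test_that("organ volumes stay below total body volume for varied individuals", {
  grid <- expand.grid(weight = c(40, 60, 73, 100, 140),
                      height = c(150, 176, 200))
  for (i in seq_len(nrow(grid))) {
    ind <- make_reference_individual(weight = grid$weight[i],
                                     height = grid$height[i])
    expect_lt(sum(ind$organs[[1]]$volume_l), grid$weight[i] / 1.05)
  }
})

test_that("flow conservation holds for every sampled individual", {
  pop <- sample_population(population_spec(20, "healthy", seed = 7))
  for (i in seq_len(nrow(pop))) {
    flows <- pop$organs[[i]]$flow_l_per_h
    expect_equal(sum(flows, na.rm = TRUE), pop$cardiac_output_l_h[i],
                 tolerance = 0.01)
    expect_true(all(pop$organs[[i]]$volume_l > 0))
    expect_true(all(flows > 0, na.rm = TRUE))
    expect_gt(pop$hematocrit[i], 0)
    expect_lt(pop$hematocrit[i], 1)
  }
})

test_that("stage means are 110 > 40 > 25 > 8 and applied to individuals", {
  stages <- renal_stages()
  expect_equal(stages$egfr_mean, c(110, 40, 25, 8))
  expect_true(all(diff(stages$egfr_mean) < 0))
  expect_true(all(stages$egfr_mean >= stages$egfr_lo &
                    stages$egfr_mean <= stages$egfr_hi))

  ind <- healthy_cohort_individual()
  mod <- apply_renal_impairment(ind, "moderate")
  expect_equal(mod$egfr, 25)
  sev <- apply_renal_impairment(ind, "severe")
  expect_equal(sev$ka_ap, 1.3)
  expect_lt(sev$gfr_abs_l_h, ind$gfr_abs_l_h)
})

test_that("healthy stage application is the identity and overrides only warn", {
  ind <- healthy_cohort_individual()
  expect_identical(apply_renal_impairment(ind, "healthy"), ind)
  expect_warning(apply_renal_impairment(ind, "healthy",
                                        modifiers = list(hematocrit = 0.3)),
                 "healthy")
})

test_that("zero-variance spec reproduces the reference individual", {
  spec <- population_spec(1, "healthy", age_cv = 0, weight_cv = 0,
                          height_cv = 0, female_fraction = 0,
                          cv_volumes = 0, cv_flows = 0,
                          egfr_range = c(110, 110), seed = 3)
  pop <- sample_population(spec)
  ref <- make_reference_individual()
  expect_equal(pop$organs[[1]], ref$organs[[1]])
  expect_equal(pop$egfr, ref$egfr)
  expect_equal(pop$weight, ref$weight)
})

test_that("population sampling is deterministic and serializes identically", {
  spec <- population_spec(15, "moderate", seed = 101)
  p1 <- sample_population(spec)
  p2 <- sample_population(spec)
  expect_identical(p1, p2)
  expect_identical(readr::format_csv(population_to_wide(p1)),
                   readr::format_csv(population_to_wide(p2)))
  expect_true(all(p1$egfr >= 15 & p1$egfr <= 30))
  expect_equal(p1$ka_ap, rep(1.3, 15))
})

test_that("sampled mean weight is within 3 SE of the target", {
  n <- 1500
  pop <- sample_population(population_spec(n, "healthy", weight_mean = 71,
                                           weight_cv = 0.10, seed = 31))
  se <- 71 * 0.10 / sqrt(n)
  expect_lt(abs(mean(pop$weight) - 71), 3 * se)
})

test_that("invalid population specs are rejected", {
  expect_error(population_spec(0, seed = 1), "n must be")
  expect_error(population_spec(5, cv_volumes = -0.1, seed = 1), "variation")
  expect_error(population_spec(5, female_fraction = 2, seed = 1),
               "female_fraction")
  expect_error(population_spec(5, egfr_range = c(50, 30), seed = 1),
               "egfr_range")
  expect_error(population_spec(5), "seed")
})
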