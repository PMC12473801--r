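test_that("packaged PRE/OBS fixtures are intact byte-for-byte", {
  sums <- c(
    table1_demographics.csv = "c95a54ea52a6a0dc64da640f0d1bdf6a",
    table3_healthy_pairs.csv = "dae15f437978649e7de9da8b563e5b69",
    table5_ri_pairs.csv = "d67caa599a1666ab041bf7e0a1fbc1d1",
    ofloxacin.yaml = "2129d6d44ff7ad9c71f9c5aa92ebd7d8"
  )
  for (f in names(sums)) {
    path <- system.file("extdata", f, package = "renopbpk")
    expect_equal(unname(tools::md5sum(path)), unname(sums[[f]]), label = f)
  }
})

test_that("pair loader returns tidy rows for all cohorts and parameters", {
  pairs <- load_pk_pairs("all")
  expect_equal(nrow(pairs), (11 + 3) * 3)
  expect_setequal(unique(pairs$parameter), c("Cmax", "AUC_0_t", "CL"))
  expect_setequal(unique(pairs$cohort),
                  c("healthy_iv", "healthy_po", "ri_mild", "ri_moderate",
                    "ri_severe"))
  expect_true(all(pairs$predicted > 0 & pairs$observed > 0))
})

test_that("predicted/observed ratios reproduce the tabulated examples", {
  expect_equal(round(ratio_pre_obs(31.49, 50.12), 2), 0.63)
  expect_equal(round(ratio_pre_obs(13.77, 10.42), 2), 1.32)
  expect_equal(ratio_pre_obs(4.2, 4.2), 1.0)
  expect_error(ratio_pre_obs(1, 0), "observed")
})

test_that("average fold error matches its reported value and symmetries", {
  pre <- c(1.91, 1.59, 1.64)
  obs <- c(1.52, 1.55, 1.57)
  expect_equal(round(afe(pre, obs), 2), 1.10)
  expect_identical(afe(obs, obs), 1)
  set.seed(8)
  a <- runif(9, 0.5, 3); b <- runif(9, 0.5, 3)
  expect_equal(afe(a, b) * afe(b, a), 1, tolerance = 1e-12)
  expect_error(afe(c(1, -1), c(1, 1)), "positive")
})

test_that("AFE of concatenated sets is the log-weighted geometric combination", {
  set.seed(12)
  a1 <- runif(4, 0.5, 2); b1 <- runif(4, 0.5, 2)
  a2 <- runif(7, 0.5, 2); b2 <- runif(7, 0.5, 2)
  combined <- afe(c(a1, a2), c(b1, b2))
  weighted <- 10^((4 * log10(afe(a1, b1)) + 7 * log10(afe(a2, b2))) / 11)
  expect_equal(combined, weighted, tolerance = 1e-12)
})

test_that("error metrics reproduce the tabulated values and closed forms", {
  pre <- c(22.32, 25.50, 31.49)
  obs <- c(28.79, 34.33, 50.12)
  expect_equal(round(mae(pre, obs), 2), 11.31)
  expect_equal(round(rmse(pre, obs), 2), 12.48, tolerance = 0.02)
  expect_equal(rmse(c(3), c(5)), 2)
  expect_equal(mae(c(3), c(5)), 2)
  expect_identical(rmse(pre, pre), 0)
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("RMSE dominates MAE for any dataset", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    a <- rnorm(n, 10, 3); b <- rnorm(n, 10, 3)
    expect_gte(rmse(a, b), mae(a, b) - 1e-12)
  }
})

test_that("metrics are invariant to pair order", {
  set.seed(5)
  a <- runif(8, 1, 5); b <- runif(8, 1, 5)
  p <- sample(8)
  expect_equal(afe(a, b), afe(a[p], b[p]))
  expect_equal(rmse(a, b), rmse(a[p], b[p]))
  expect_equal(mae(a, b), mae(a[p], b[p]))
})

test_that("ratio summaries use t intervals for n >= 3 and ranges below", {
  r <- c(0.9, 1.1, 1.3, 0.8, 1.05)
  rs <- ratio_summary(r)
  oracle <- t.test(r)  # independent CI computation
  expect_equal(c(rs$lo, rs$hi), as.numeric(oracle$conf.int), tolerance = 1e-9)
  expect_equal(rs$mean_R, mean(r))
  expect_false(rs$small_n)
  expect_true(rs$lo <= rs$mean_R && rs$mean_R <= rs$hi)

  one <- ratio_summary(1.2)
  expect_equal(one$mean_R, 1.2)
  expect_equal(one$lo, one$hi)
  expect_true(one$small_n)
  two <- ratio_summary(c(0.8, 1.2))
  expect_equal(two$mean_R, 1.0)
  expect_equal(c(two$lo, two$hi), c(0.8, 1.2))
})

test_that("the 0.5-2 fold band is inclusive at both bounds", {
  d <- tibble::tibble(predicted = c(1, 2, 0.5, 2.01), observed = rep(1, 4))
  fe <- fold_error_within(d)
  expect_equal(fe$within, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("the evaluation report aggregates per cohort and parameter", {
  rep <- evaluate_pairs(load_pk_pairs("all"))
  expect_equal(nrow(rep), 5 * 3)
  expect_true(all(rep$AFE > 0))
  expect_true(all(rep$R_lo <= rep$mean_R & rep$mean_R <= rep$R_hi))
  td <- tidy(rep)
  expect_equal(nrow(td), 42)
  expect_true(all(c("fold_error", "within") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$n, 42)
  expect_true(gl$prop_within_2fold > 0.9)
})
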