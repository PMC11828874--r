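test_that("simulated spectra always sum to the requested cell number", {
  set.seed(1)
  for (r in 1:20) {
    n <- sample(1:5000, 1)
    d <- simulate_distribution(true_theta, runif(1, 0, 5), n,
                               dispersion = sample(c(1, 1.2), 1))
    expect_equal(sum(d$counts), n)
  }
})

test_that("zero mean yields all-zero cells", {
  d <- simulate_distribution(c(0, 0, 0), dose = 0, n_cells = 50)
  expect_equal(d$dicentrics, 0)
  d2 <- simulate_distribution(c(0, 0.05, 0.01), dose = 0, n_cells = 50)
  expect_equal(d2$dicentrics, 0)
})

test_that("empirical yield matches C + alpha*D + beta*D^2 within 3 SE", {
  set.seed(2)
  n <- 1e5
  d <- simulate_distribution(c(0.001, 0.02, 0.06), 3, n)
  y <- 0.001 + 0.02 * 3 + 0.06 * 9  # 0.601 by hand
  expect_equal(y, 0.601)
  se <- sqrt(y / n)
  expect_lt(abs(d$dicentrics / n - y), 3 * se)
})

test_that("Poisson cells have dispersion index near 1, gamma-mixed near target", {
  set.seed(3)
  n <- 1e5
  d1 <- simulate_distribution(c(0.001, 0.02, 0.06), 3, n, dispersion = 1)
  # SE of the variance/mean ratio of Poisson counts ~ sqrt(2/n) + mean term
  expect_lt(abs(dispersion_index(d1) - 1), 3 * sqrt(2 / n + 1 / (n * 0.601)))
  d2 <- simulate_distribution(c(0.001, 0.02, 0.06), 3, n, dispersion = 1.15)
  expect_gt(dispersion_index(d2), 1.10)
  expect_lt(dispersion_index(d2), 1.20)
})

test_that("simulation rejects invalid inputs", {
  expect_error(simulate_distribution(true_theta, -1, 100), "non-negative")
  expect_error(simulate_distribution(true_theta, 1, 0), "at least 1")
  expect_error(simulate_distribution(true_theta, 1, 100, dispersion = 0.8),
               ">= 1")
  expect_error(simulate_distribution(c(-0.1, 0.02, 0.06), 1, 100),
               "non-negative")
})

test_that("lab profiles respect configured ranges; degenerate ranges are exact", {
  cfg <- ilc_config(alpha_range = c(0.01, 0.069), beta_range = c(0.031, 0.097),
                    fraction_semi_automatic = 0, seed = 5)
  set.seed(5)
  for (r in 1:50) {
    p <- sample_lab_profile(cfg, "Lx")
    expect_gte(p$alpha, 0.01); expect_lte(p$alpha, 0.069)
    expect_gte(p$beta, 0.031); expect_lte(p$beta, 0.097)
    expect_identical(p$scoring_mode, "manual")
    expect_identical(p$dispersion, 1)
  }
  cfg2 <- ilc_config(alpha_range = c(0.05, 0.05), fraction_semi_automatic = 0)
  set.seed(6)
  expect_equal(sample_lab_profile(cfg2)$alpha, 0.05)
  # semi-automatic labs draw dispersion from their own range
  cfg3 <- ilc_config(fraction_semi_automatic = 1,
                     semi_auto_dispersion_range = c(1.05, 1.15))
  set.seed(7)
  p3 <- sample_lab_profile(cfg3)
  expect_identical(p3$scoring_mode, "semi_automatic")
  expect_gte(p3$dispersion, 1.05); expect_lte(p3$dispersion, 1.15)
})

test_that("config validation catches malformed ranges and doses", {
  expect_error(ilc_config(alpha_range = c(0.05, 0.01)), "ranges")
  expect_error(ilc_config(blind_doses_air_kerma = numeric(0)), "non-empty")
  expect_error(ilc_config(blind_doses_air_kerma = c(2, -1)), "positive")
  expect_error(ilc_config(semi_auto_dispersion_range = c(0.9, 1.2)), ">= 1")
  expect_error(ilc_config(calibration_doses = c(0, 2, 1)), "increasing")
  expect_error(ilc_config(bias_factors = 0), "positive")
})

test_that("identical seeds reproduce the ILC exactly; different seeds differ", {
  cfg <- ilc_config(n_labs = 4, seed = 11)
  s1 <- simulate_ilc(cfg)
  s2 <- simulate_ilc(cfg)
  expect_identical(s1$calibration, s2$calibration)
  expect_identical(s1$blind, s2$blind)
  s3 <- simulate_ilc(ilc_config(n_labs = 4, seed = 12))
  expect_false(identical(s1$blind, s3$blind))
})

test_that("per-lab sub-streams are independent of the number of labs", {
  a <- simulate_ilc(ilc_config(n_labs = 3, seed = 8))
  b <- simulate_ilc(ilc_config(n_labs = 6, seed = 8))
  expect_identical(a$blind[["L2"]], b$blind[["L2"]])
  expect_identical(a$calibration[["L3"]], b$calibration[["L3"]])
})

test_that("simulated ILC has the advertised cardinality and ground truth", {
  sim <- simulate_ilc(ilc_config(n_labs = 14, seed = 21))
  expect_length(sim$blind, 14)
  expect_true(all(lengths(sim$blind) == 3))
  refs <- sim$truth$references
  expect_equal(refs$dose_to_blood, refs$air_kerma *
                 sim$config$kerma_to_blood_factor)
  # blinded payload carries no dose
  expect_true(all(is.na(vapply(sim$blind[[1]], `[[`, numeric(1), "dose"))))
})

test_that("an air-kerma lab scores the blind sample on its own dose scale", {
  # with the dose-to-blood factor 2.71/2.56, a lab calibrated in air kerma
  # sees the first blind sample at 2.56 Gy on its own scale
  cfg <- ilc_config(n_labs = 1, fraction_semi_automatic = 0,
                    cells_manual = 50000,
                    dose_definition_prob = c(air_kerma = 1, dose_to_water = 0,
                                             dose_to_blood = 0),
                    seed = 13)
  sim <- simulate_ilc(cfg)
  prof <- sim$labs[[1]]
  y_obs <- sim$blind[[1]][["S1"]]$dicentrics / sim$blind[[1]][["S1"]]$n_cells
  y_exp <- prof$background + prof$alpha * 2.56 + prof$beta * 2.56^2
  expect_lt(abs(y_obs - y_exp), 3 * sqrt(y_exp / 50000))
  # a dose-to-water lab sees the same sample at 2.71 Gy on its scale
  cfgw <- ilc_config(n_labs = 1, fraction_semi_automatic = 0,
                     cells_manual = 50000,
                     dose_definition_prob = c(air_kerma = 0, dose_to_water = 1,
                                              dose_to_blood = 0),
                     seed = 13)
  simw <- simulate_ilc(cfgw)
  profw <- simw$labs[[1]]
  yw_obs <- simw$blind[[1]][["S1"]]$dicentrics / simw$blind[[1]][["S1"]]$n_cells
  yw_exp <- profw$background + profw$alpha * 2.71 + profw$beta * 2.71^2
  expect_lt(abs(yw_obs - yw_exp), 3 * sqrt(yw_exp / 50000))
})

test_that("the full chain recovers doses without bias when labs are unbiased", {
  cfg <- ilc_config(n_labs = 6, fraction_semi_automatic = 0,
                    cells_manual = 20000, seed = 17)
  run <- run_ilc(simulate_ilc(cfg))
  rep <- evaluate_ilc(run$submissions, run$references, mode = "matching")
  # 20k cells per sample: each lab's estimate should sit close to its
  # matching reference, so the mean deviation is tiny
  expect_lt(max(abs(rep$fractions$mean_deviation)), 0.06)
  expect_true(all(rep$per_lab$bias_class == "none"))
  expect_true(all(rep$per_lab$ranking_correct))
})
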