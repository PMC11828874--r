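make_refs <- function() {
  data.frame(sample_id = c("S1", "S2", "S3"),
             air_kerma = c(2.56, 3.41, 4.54),
             dose_to_blood = c(2.71, 3.60, 4.80))
}

test_that("select_reference honours the comparison mode", {
  refs <- make_refs()
  r1 <- refs[1, ]
  expect_equal(select_reference(r1, "dose_to_water", mode = "air_kerma"), 2.56)
  expect_equal(select_reference(r1, "air_kerma", mode = "dose_to_blood"), 2.71)
  # matching groups water with blood
  expect_equal(select_reference(r1, "dose_to_water", mode = "matching"), 2.71)
  expect_equal(select_reference(r1, "air_kerma", mode = "matching"), 2.56)
  expect_error(select_reference(r1, "air_kerma", mode = "kerma"))
})

test_that("z score arithmetic, antisymmetry and flags", {
  expect_equal(z_score(3.0, 2.56, 0.22), 2.0)
  expect_equal(z_score(2.56, 2.56, 0.5), 0)
  expect_equal(z_score(2.0, 2.56, 0.22), -z_score(3.12, 2.56, 0.22))
  expect_error(z_score(3, 2.56, 0), "positive")
})

test_that("proficiency sigma rules", {
  expect_equal(proficiency_sigma(c(2.0, 2.5, 3.0)), 0.7413)
  expect_equal(proficiency_sigma(c(2, 3), rule = "fixed", reference = 3.41),
               0.341)
  expect_equal(proficiency_sigma(c(2, 3), rule = "ci",
                                 ci_low = c(1.5, 2.4), ci_high = c(2.5, 3.6)),
               c(1, 1.2) / (2 * qnorm(0.975)))
  expect_error(proficiency_sigma(c(2, 3)), "at least 3")
  # degenerate spread cascades into a z-score error
  expect_equal(proficiency_sigma(c(2, 2, 2)), 0)
  expect_error(z_score(2, 2.5, proficiency_sigma(c(2, 2, 2))), "positive")
})

test_that("systematic bias rule needs consistent sign and >= 2 CI exclusions", {
  expect_identical(classify_bias(c(0.3, 0.4, 0.2), c(TRUE, TRUE, FALSE)),
                   "systematic_over")
  expect_identical(classify_bias(c(-0.3, -0.4, -0.2), c(TRUE, FALSE, TRUE)),
                   "systematic_under")
  expect_identical(classify_bias(c(0.3, 0.4, 0.2), c(FALSE, FALSE, FALSE)),
                   "none")
  expect_identical(classify_bias(c(0.3, 0.4, 0.2), c(TRUE, FALSE, FALSE)),
                   "none")
  expect_identical(classify_bias(c(0.3, -0.4, 0.2), c(TRUE, TRUE, TRUE)),
                   "none")
  expect_identical(classify_bias(c(0.3, NA, 0.2), c(TRUE, NA, TRUE)),
                   "not_classifiable")
})

test_that("triage categories use the 1-2 Gy closed middle band", {
  expect_identical(triage_category(c(0, 0.99, 1.0, 1.5, 2.0, 2.01, 2.9, 4.8)),
                   c("low", "low", "medium", "medium", "medium", "high",
                     "high", "high"))
  expect_error(triage_category(-0.1), "non-negative")
})

test_that("band check is closed at the boundary", {
  expect_true(within_band(3.3, 3.41))
  expect_false(within_band(4.42, 3.41))
  expect_true(within_band(4.41, 3.41))
  expect_true(within_band(3.41, 3.41, band = 1e-9))
  expect_error(within_band(3, 3, band = 0), "positive")
})

test_that("ranking requires a strict matching order", {
  refs <- c(2.56, 3.41, 4.54)
  expect_true(ranking_correct(c(2.7, 3.5, 4.6), refs))
  expect_false(ranking_correct(c(3.5, 2.7, 4.6), refs))
  expect_false(ranking_correct(c(2.7, 2.7, 4.6), refs))
  expect_error(ranking_correct(c(2.7, 3.5), refs), "same samples")
})

test_that("between-sample correlation over paired labs", {
  a <- c(L1 = 1, L2 = 2, L3 = 3)
  expect_equal(estimate_correlation(a, a)$r, 1)
  expect_equal(estimate_correlation(a, c(L1 = 2, L2 = 4, L3 = 6))$r, 1)
  expect_equal(estimate_correlation(a, -a)$r, -1)
  expect_error(estimate_correlation(a[1:2], a[1:2]), "at least 3")
  b <- c(L1 = 3.1, L2 = 2.8, L4 = 3.4)  # only L1, L2 shared
  expect_error(estimate_correlation(a, b), "at least 3")
})

test_that("a clean single-lab fixture scores perfectly", {
  refs <- make_refs()
  subs <- data.frame(
    lab_id = "L1", sample_id = c("S1", "S2", "S3"),
    dose = c(2.6, 3.5, 4.6),
    ci_low = c(2.1, 3.0, 4.1), ci_high = c(3.1, 4.0, 5.1),
    dose_definition = "air_kerma")
  rep <- evaluate_ilc(subs, refs, mode = "air_kerma", sigma_rule = "ci")
  expect_equal(rep$fractions$frac_ci_contains_reference, rep(1, 3))
  expect_true(all(rep$per_lab$bias_class == "none"))
  expect_true(all(rep$per_lab$ranking_correct))
  expect_true(all(rep$per_sample$triage == "high"))
  expect_true(all(rep$per_sample$within_band))
})

test_that("report fractions are invariant to lab ordering and relabeling", {
  set.seed(61)
  refs <- make_refs()
  labs <- paste0("L", 1:6)
  subs <- expand.grid(lab_id = labs, sample_id = refs$sample_id,
                      stringsAsFactors = FALSE)
  subs$dose <- refs$air_kerma[match(subs$sample_id, refs$sample_id)] +
    rnorm(nrow(subs), 0, 0.3)
  subs$ci_low <- subs$dose - 0.5
  subs$ci_high <- subs$dose + 0.5
  subs$dose_definition <- "air_kerma"
  r1 <- evaluate_ilc(subs, refs, mode = "air_kerma")
  shuffled <- subs[sample(nrow(subs)), ]
  r2 <- evaluate_ilc(shuffled, refs, mode = "air_kerma")
  expect_equal(r1$fractions$frac_ci_contains_reference,
               r2$fractions$frac_ci_contains_reference)
  expect_equal(r1$fractions$mean_deviation, r2$fractions$mean_deviation)
  relabeled <- subs
  relabeled$lab_id <- chartr("123456", "654321", relabeled$lab_id)
  r3 <- evaluate_ilc(relabeled, refs, mode = "air_kerma")
  expect_equal(r1$fractions$frac_ci_contains_reference,
               r3$fractions$frac_ci_contains_reference)
})

test_that("ci_contains_reference matches the interval check row by row", {
  set.seed(62)
  refs <- make_refs()
  subs <- expand.grid(lab_id = paste0("L", 1:5), sample_id = refs$sample_id,
                      stringsAsFactors = FALSE)
  subs$dose <- runif(nrow(subs), 2, 5)
  subs$ci_low <- subs$dose - runif(nrow(subs), 0.1, 0.8)
  subs$ci_high <- subs$dose + runif(nrow(subs), 0.1, 0.8)
  subs$dose_definition <- sample(c("air_kerma", "dose_to_water"),
                                 nrow(subs), replace = TRUE)
  for (m in c("air_kerma", "dose_to_blood", "matching")) {
    rep <- evaluate_ilc(subs, refs, mode = m)
    ps <- rep$per_sample
    expect_equal(ps$ci_contains_reference,
                 ps$ci_low <= ps$reference & ps$reference <= ps$ci_high)
  }
})

test_that("bias classification is antisymmetric under reflection", {
  refs <- make_refs()
  base <- data.frame(
    lab_id = "L1", sample_id = refs$sample_id,
    dose = refs$air_kerma + c(0.45, 0.5, 0.55),
    dose_definition = "air_kerma")
  base$ci_low <- base$dose - 0.4
  base$ci_high <- base$dose + 0.4
  # pad with two neutral labs so the robust sigma rule applies
  pad <- do.call(rbind, lapply(c("L2", "L3"), function(l) {
    p <- base; p$lab_id <- l
    p$dose <- refs$air_kerma + c(-0.02, 0.01, 0.02) * (1 + (l == "L3"))
    p$ci_low <- p$dose - 1; p$ci_high <- p$dose + 1
    p
  }))
  over <- evaluate_ilc(rbind(base, pad), refs, mode = "air_kerma")
  expect_identical(
    over$per_lab$bias_class[over$per_lab$lab_id == "L1"], "systematic_over")
  reflected <- base
  reflected$dose <- 2 * refs$air_kerma - base$dose
  reflected$ci_low <- reflected$dose - 0.4
  reflected$ci_high <- reflected$dose + 0.4
  under <- evaluate_ilc(rbind(reflected, pad), refs, mode = "air_kerma")
  expect_identical(
    under$per_lab$bias_class[under$per_lab$lab_id == "L1"],
    "systematic_under")
})

test_that("unbiased Poisson ILCs rarely produce questionable Z-scores", {
  set.seed(63)
  n_ilc <- 40
  shares <- numeric(n_ilc)
  seeds <- sample.int(2^31 - 1, n_ilc)
  for (i in seq_len(n_ilc)) {
    cfg <- ilc_config(n_labs = 8, fraction_semi_automatic = 0,
                      seed = seeds[i])
    run <- run_ilc(simulate_ilc(cfg))
    rep <- evaluate_ilc(run$submissions, run$references, mode = "matching")
    shares[i] <- mean(rep$per_sample$z_flag != "satisfactory")
  }
  expect_lt(mean(shares), 0.10)
})
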