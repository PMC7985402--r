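test_that("cohort specs are validated with errors naming the field", {
  m <- tiny_montage(2)
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(n_subjects = 5, sample_rate = 512,
                           duration = 0.0013),
               "integer sample count")
  osc <- oscillator_spec("a", 10, topography = flat_topo(m))
  expect_error(
    cohort_spec(n_subjects = 5, montage = m, oscillators = list(osc),
                couplings = list(effect_spec("s", "missing_osc", 1))),
    "unknown oscillator 'missing_osc'"
  )
  expect_error(
    cohort_spec(n_subjects = 5, montage = tiny_montage(3),
                oscillators = list(osc)),
    "topography lacks channel"
  )
  expect_error(oscillator_spec("a", 70, topography = flat_topo(m)),
               "center_frequency")
  expect_error(oscillator_spec("a", 10, bandwidth = -1,
                               topography = flat_topo(m)),
               "bandwidth")
  expect_error(effect_spec("s", "a", 1, noise_sd = -2), "noise_sd")
})

test_that("generation is bit-identical under a repeated seed", {
  spec <- cohort_preset("desk", n_subjects = 12, seed = 77)
  a <- simulate_feature_cohort(spec)
  b <- simulate_feature_cohort(spec)
  expect_identical(a, b)

  spec_t <- cohort_spec(n_subjects = 3, montage = tiny_montage(2),
                        duration = 2, seed = 5, null_outcomes = "score")
  t1 <- simulate_cohort(spec_t)
  t2 <- simulate_cohort(spec_t)
  expect_identical(t1$recordings$signals, t2$recordings$signals)
  expect_identical(t1$subjects, t2$subjects)
})

test_that("the full-scale feature cohort has the reference dimensions", {
  co <- simulate_feature_cohort(cohort_spec(n_subjects = 216, seed = 1))
  expect_equal(dim(co$features), c(216, 1 + 3200))
  expect_equal(nrow(co$subjects), 216)
  expect_true(all(spectralforest:::symptom_dimension_names() %in%
                    names(co$subjects)))
})

test_that("null cohorts carry no outcome-feature coupling", {
  spec <- cohort_preset("desk", seed = 31)
  co <- simulate_feature_cohort(spec)
  X <- spectralforest:::feature_matrix(co$features)
  r <- as.numeric(cor(co$subjects$score, X))
  # max |r| over 200 features at n = 60 under the null: sd(r) ~ 1/sqrt(57),
  # so the largest of 200 should stay well under 0.55
  expect_lt(max(abs(r)), 0.55)
  expect_lt(abs(mean(r)), 0.05)
})

test_that("a noiseless coupling makes the outcome an affine image of the latent", {
  m <- tiny_montage(2)
  osc <- oscillator_spec("alpha", 10, 2, mean_log_power = 3,
                         between_subject_sd = 0.8,
                         topography = flat_topo(m))
  spec <- cohort_spec(n_subjects = 50, montage = m, duration = 2,
                      oscillators = list(osc),
                      couplings = list(effect_spec("score", "alpha", 1,
                                                   noise_sd = 0)),
                      seed = 3)
  co <- simulate_feature_cohort(spec)
  expect_equal(cor(co$subjects$score, co$latents$alpha), 1,
               tolerance = 1e-12)
})

test_that("time-domain synthesis agrees with the latent band-power model", {
  m <- tiny_montage(4)
  osc <- oscillator_spec("alpha", 10, 2, mean_log_power = 3,
                         between_subject_sd = 0.8,
                         topography = flat_topo(m))
  spec <- cohort_spec(n_subjects = 8, montage = m, duration = 30,
                      oscillators = list(osc),
                      couplings = list(effect_spec("score", "alpha", 1,
                                                   noise_sd = 0)),
                      seed = 5)
  co <- simulate_cohort(spec)
  ft <- spectral_features(co$recordings)
  X <- spectralforest:::feature_matrix(ft)

  # extracted 10 Hz log power tracks the latent (hence the outcome)
  expect_gt(cor(co$latents$alpha, X[, "Fp1_10Hz"]), 0.9)
  expect_gt(cor(co$subjects$score, X[, "Fp1_10Hz"]), 0.9)

  # the oscillator bin exceeds the out-of-band neighbours by a margin
  # predicted from the latent model (within loose Monte-Carlo tolerance)
  bg <- spectralforest:::background_log_power(spec, 1:50)
  bump <- spectralforest:::oscillator_bump(osc, 1:50)
  predicted_margin <- (bg[10] + bump[10] * 3) - (bg[7] + bump[7] * 3)
  observed_margin <- mean(X[, "Fp1_10Hz"]) - mean(X[, "Fp1_7Hz"])
  expect_gt(observed_margin, predicted_margin / 2)
})

test_that("an all-zero topography leaves the oscillator bin at background", {
  m <- tiny_montage(2)
  osc <- oscillator_spec("alpha", 10, 2, mean_log_power = 3,
                         between_subject_sd = 0.5,
                         topography = flat_topo(m, 0))
  spec <- cohort_spec(n_subjects = 100, montage = m, duration = 2,
                      oscillators = list(osc), measurement_sd = 0.3,
                      seed = 6)
  co <- simulate_feature_cohort(spec)
  X <- spectralforest:::feature_matrix(co$features)
  bg <- spectralforest:::background_log_power(spec, 1:50)
  se <- 0.3 / sqrt(100)
  expect_lt(abs(mean(X[, "Fp1_10Hz"]) - bg[10]), 4 * se)
})

test_that("a planted age slope on power is recovered by per-bin regression", {
  spec <- cohort_spec(n_subjects = 200, montage = tiny_montage(2),
                      duration = 2, age_slope = 0.02, measurement_sd = 0.4,
                      seed = 8)
  co <- simulate_feature_cohort(spec)
  X <- spectralforest:::feature_matrix(co$features)
  for (col in c("Fp1_3Hz", "Fpz_25Hz", "Fp1_48Hz")) {
    fit <- summary(lm(X[, col] ~ co$subjects$age))
    est <- fit$coefficients[2, "Estimate"]
    se <- fit$coefficients[2, "Std. Error"]
    expect_lt(abs(est - 0.02), 2 * se)
  }
})

test_that("demographics and labels follow the configured cohort model", {
  co <- simulate_feature_cohort(cohort_spec(n_subjects = 2000, seed = 9))
  s <- co$subjects
  expect_true(all(s$age >= 12.6 & s$age <= 64.6))
  expect_lt(abs(mean(s$age) - 38.6), 1)
  expect_lt(abs(mean(s$gender) - 0.384), 0.04)
  expect_true(all(s$diagnosis %in% c("MDD", "BP", "PSY", "OCD", "GAD",
                                     "ASD", "ID-NOS")))
  expect_lt(abs(mean(s$diagnosis == "ID-NOS") - 101 / 216), 0.04)
})

test_that("floored outcomes never go negative", {
  m <- tiny_montage(2)
  osc <- oscillator_spec("o", 10, topography = flat_topo(m),
                         mean_log_power = 0, between_subject_sd = 1)
  spec <- cohort_spec(n_subjects = 200, montage = m, duration = 2,
                      oscillators = list(osc),
                      couplings = list(effect_spec("errors", "o", 1,
                                                   noise_sd = 1)),
                      outcome_floor = "errors", seed = 10)
  co <- simulate_feature_cohort(spec)
  expect_true(all(co$subjects$errors >= 0))
  expect_gt(mean(co$subjects$errors == 0), 0.1)
})
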