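test_that("permutation p-values reproduce the printed worked examples", {
  expect_identical(permutation_p(11, 2000), 0.0055)
  expect_identical(permutation_p(13, 2000), 0.0065)
  expect_identical(permutation_p(14, 2000), 0.007)
  expect_identical(permutation_p(2000, 2000), 1)
  expect_identical(permutation_p(0, 500), 0)
  expect_equal(permutation_p(11, 2000, method = "add-one"), 12 / 2001)
  expect_error(permutation_p(5, 0), "n_permutations")
  expect_error(permutation_p(10, 5), "cannot exceed")
})

test_that("Bonferroni threshold matches the analysis convention", {
  expect_equal(signif(bonferroni_threshold(0.05, 7), 3), 0.00714)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_identical(bonferroni_threshold(0.01, 4), 0.0025)
})

test_that("frequency profile averages importance across electrodes", {
  m <- tiny_montage(4)
  nm <- feature_names(m)
  flat <- tibble::tibble(feature = nm, importance = rep(3.5, length(nm)))
  prof <- frequency_profile(flat)
  expect_equal(nrow(prof), 50)
  expect_true(all(prof$importance == 3.5))

  spike <- tibble::tibble(feature = nm, importance = 0)
  spike$importance[spike$feature == sprintf("%s_13Hz", m$channel[2])] <- 8
  prof2 <- frequency_profile(spike)
  expect_equal(prof2$importance[prof2$freq == 13], 8 / 4)
  expect_true(all(prof2$importance[prof2$freq != 13] == 0))

  withr::with_seed(1, rand <- tibble::tibble(feature = nm,
                                             importance = rnorm(length(nm))))
  prof3 <- frequency_profile(rand)
  info <- parse_features(nm)
  for (fr in c(1, 17, 50)) {
    expect_equal(prof3$importance[prof3$freq == fr],
                 mean(rand$importance[info$freq == fr]), tolerance = 1e-12)
  }

  expect_error(frequency_profile(rand[-5, ]), "missing")
})

test_that("peak selection follows the local-maximum + 1 SD rule", {
  expect_length(find_peaks(rep(2, 50)), 0)

  spike <- rep(0, 50)
  spike[17] <- 10
  expect_identical(find_peaks(spike), 17)

  # brute-force scan oracle applied literally, on profiles with plateaus
  brute <- function(v) {
    cut <- mean(v) + sd(v)
    out <- c()
    for (i in seq_along(v)) {
      lok <- i == 1 || v[i] > v[i - 1]
      rok <- i == length(v) || v[i] > v[i + 1]
      if (lok && rok && v[i] > cut) out <- c(out, i)
    }
    as.numeric(if (is.null(out)) numeric(0) else out)
  }
  withr::with_seed(5, {
    for (rep in 1:50) {
      v <- round(rnorm(50), 1)  # rounding creates plateaus and ties
      expect_identical(find_peaks(v), brute(v))
    }
  })
})

test_that("peak selection is invariant to shifting and positive rescaling", {
  withr::with_seed(6, v <- rnorm(50)^2)
  base <- find_peaks(v)
  expect_identical(find_peaks(v + 100), base)
  expect_identical(find_peaks(v * 7), base)
})

test_that("edge bins can be peaks over their single neighbour", {
  v <- rep(0, 50)
  v[1] <- 5
  expect_identical(find_peaks(v), 1)
  v2 <- rep(0, 50)
  v2[50] <- 5
  expect_identical(find_peaks(v2), 50)
})

test_that("permutation test is seed-reproducible with a valid p convention", {
  withr::with_seed(7, {
    X <- matrix(rnorm(30 * 10), 30)
    colnames(X) <- paste0("f", 1:10)
    y <- 2 * X[, 1] + rnorm(30, 0, 0.5)
  })
  cfg <- forest_config(n_trees = 60, mtry = 3, seed = 2)
  p1 <- permutation_test(X, y, cfg, n_permutations = 40, seed = 5)
  p2 <- permutation_test(X, y, cfg, n_permutations = 40, seed = 5)
  expect_identical(p1$null_nse, p2$null_nse)
  expect_identical(p1$p_value, p2$p_value)
  expect_identical(p1$p_value,
                   sum(p1$null_nse >= p1$observed_nse) / 40)
  # p is antitone in the observed statistic for a fixed null sample
  weaker <- sum(p1$null_nse >= p1$observed_nse - 0.2) / 40
  expect_gte(weaker, p1$p_value)
})

test_that("a planted association is detected by the permutation test", {
  withr::with_seed(8, {
    X <- matrix(rnorm(40 * 20), 40)
    colnames(X) <- paste0("f", 1:20)
    y <- 2 * X[, 3] + rnorm(40, 0, 0.4)
  })
  pt <- permutation_test(X, y, forest_config(n_trees = 150, mtry = 5,
                                             seed = 1),
                         n_permutations = 100, seed = 3)
  expect_lte(pt$p_value, 0.02)
  expect_gt(pt$observed_nse, max(pt$null_nse))
})

test_that("direction-of-effect betas are signed standardized coefficients", {
  m <- tiny_montage(4)
  withr::with_seed(9, {
    X <- random_features(200, m, seed = 12)
    imp <- tibble::tibble(feature = colnames(X), importance = 0)
    imp$importance[imp$feature == "Fp1_10Hz"] <- 5
    imp$importance[imp$feature == "Fpz_10Hz"] <- 4
    imp$importance[imp$feature == "Fp2_10Hz"] <- 3
  })
  # outcome identical to the top feature: beta exactly 1
  eff <- suppressWarnings(  # perfect fit: summary.lm warns
    direction_of_effect(X, X[, "Fp1_10Hz"], imp, 10, k_top = 1)
  )
  expect_equal(eff$beta, 1, tolerance = 1e-8)
  expect_identical(eff$channel, "Fp1")

  # negative association with noise: beta near -1
  withr::with_seed(10, yneg <- -X[, "Fp1_10Hz"] + rnorm(200, 0, 0.1))
  eff2 <- direction_of_effect(X, yneg, imp, 10, k_top = 3)
  expect_equal(eff2$beta[1], -1, tolerance = 0.05)
  expect_identical(eff2$channel, c("Fp1", "Fpz", "Fp2"))
  expect_true(all(abs(eff2$beta) <= 1))

  expect_error(direction_of_effect(X, yneg, imp, 10, k_top = 9),
               "exceeds")
  expect_error(direction_of_effect(X, yneg, imp, 99), "no features")
})

test_that("permutation and importance surfaces compose on a planted cohort", {
  m <- tiny_montage(4)
  osc <- oscillator_spec("theta", 6, 2, mean_log_power = 2,
                         between_subject_sd = 1,
                         topography = flat_topo(m))
  spec <- cohort_spec(n_subjects = 80, montage = m, duration = 10,
                      oscillators = list(osc),
                      couplings = list(effect_spec("score", "theta", -1,
                                                   noise_sd = 0.8)),
                      seed = 21)
  co <- simulate_feature_cohort(spec)
  res <- fit_residualize(co$features, co$subjects$age, co$subjects$gender)
  cfg <- forest_config(n_trees = 400, mtry = 12, seed = 2)
  fo <- fit_forest(res$features, co$subjects$score, cfg)
  prof <- frequency_profile(fo)
  pks <- find_peaks(prof)
  expect_true(any(abs(pks - 6) <= 1))
  eff <- direction_of_effect(res$features, co$subjects$score, fo,
                             pks[which.min(abs(pks - 6))])
  expect_true(all(eff$beta < 0))
})
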