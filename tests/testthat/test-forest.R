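test_that("NSE matches its definition on worked cases", {
  expect_identical(nse(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(nse(c(1, 2, 3, 4), rep(2.5, 4)), 0, tolerance = 1e-15)
  # hand case: residual SS 6 vs total SS 5 -> worse than the mean
  expect_equal(nse(c(1, 2, 3, 4), rep(2, 4)), 1 - 6 / 5, tolerance = 1e-12)
  expect_lt(nse(c(1, 2, 3, 4), rep(2, 4)), 0)
})

test_that("NSE is invariant under joint affine transformation", {
  withr::with_seed(1, {
    obs <- rnorm(30)
    pred <- obs + rnorm(30, 0, 0.5)
  })
  base <- nse(obs, pred)
  expect_equal(nse(3 + 2 * obs, 3 + 2 * pred), base, tolerance = 1e-12)
})

test_that("NSE rejects degenerate inputs", {
  expect_error(nse(rep(1, 5), rnorm(5)), "constant")
  expect_error(nse(1:3, 1:4), "equal length")
  expect_error(nse(c(1, NA, 3), c(1, 2, 3)), "non-finite")
})

test_that("forests are reproducible from the seed", {
  d <- planted_data(seed = 4)
  cfg <- forest_config(n_trees = 200, mtry = 7, seed = 99)
  f1 <- fit_forest(d$X, d$y, cfg)
  f2 <- fit_forest(d$X, d$y, cfg)
  expect_identical(f1$oob_predictions, f2$oob_predictions)
  expect_identical(f1$importance, f2$importance)
  expect_identical(f1$nse, f2$nse)
  f3 <- fit_forest(d$X, d$y, forest_config(n_trees = 200, mtry = 7,
                                           seed = 100))
  expect_false(identical(f1$oob_predictions, f3$oob_predictions))
})

test_that("OOB predictions are unchanged by skipping importance", {
  d <- planted_data(seed = 5)
  cfg <- forest_config(n_trees = 150, mtry = 7, seed = 3)
  with_imp <- fit_forest(d$X, d$y, cfg, importance = TRUE)
  without <- fit_forest(d$X, d$y, cfg, importance = FALSE)
  expect_identical(with_imp$oob_predictions, without$oob_predictions)
})

test_that("pure-noise outcomes give OOB NSE near or below zero", {
  nses <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      X <- matrix(rnorm(60 * 50), 60)
      colnames(X) <- paste0("f", 1:50)
      y <- rnorm(60)
    })
    fit_forest(X, y, forest_config(n_trees = 300, mtry = 7, seed = s),
               importance = FALSE)$nse
  }, numeric(1))
  expect_lt(mean(nses), 0.02)
})

test_that("a deterministic single-feature signal is learned", {
  withr::with_seed(2, {
    X <- matrix(rnorm(100 * 5), 100)
    colnames(X) <- paste0("f", 1:5)
    y <- ifelse(X[, 3] > 0, 2, 0)
  })
  f <- fit_forest(X, y, forest_config(n_trees = 1000, mtry = 2, seed = 1),
                  importance = FALSE)
  expect_gt(f$nse, 0.5)
})

test_that("OOB NSE stabilizes with ensemble size", {
  d <- planted_data(n = 80, seed = 6)
  n2 <- fit_forest(d$X, d$y, forest_config(n_trees = 2000, mtry = 7,
                                           seed = 42),
                   importance = FALSE)$nse
  n4 <- fit_forest(d$X, d$y, forest_config(n_trees = 4000, mtry = 7,
                                           seed = 42),
                   importance = FALSE)$nse
  expect_lt(abs(n2 - n4), 0.01)
})

test_that("a feature never used by any split has importance exactly zero", {
  withr::with_seed(3, {
    X <- cbind(sig = rnorm(40), noise = rnorm(40), flat = rep(1, 40))
    y <- X[, "sig"] * 2 + rnorm(40, 0, 0.1)
  })
  f <- suppressWarnings(
    fit_forest(X, y, forest_config(n_trees = 300, mtry = 3, seed = 1))
  )
  expect_identical(
    f$importance$importance[f$importance$feature == "flat"], 0
  )
  expect_identical(
    f$importance$mean_delta_error[f$importance$feature == "flat"], 0
  )
})

test_that("the planted feature dominates importance across seeds", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(2000 + s, {
      X <- matrix(rnorm(60 * 201), 60)
      colnames(X) <- c("planted", paste0("noise", 1:200))
      y <- 2 * X[, "planted"] + rnorm(60, 0, 0.5)
    })
    f <- fit_forest(X, y, forest_config(n_trees = 500, mtry = 14, seed = s))
    f$importance$feature[which.max(f$importance$importance)] == "planted"
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("importance estimates grow less variable with more trees", {
  seeds <- 1:10
  sd_at <- vapply(c(500, 2000, 8000), function(nt) {
    imps <- vapply(seeds, function(s) {
      withr::with_seed(77, {
        X <- matrix(rnorm(60 * 30), 60)
        colnames(X) <- paste0("f", 1:30)
        y <- 1.5 * X[, 7] + rnorm(60, 0, 0.8)
      })
      f <- fit_forest(X, y, forest_config(n_trees = nt, mtry = 6, seed = s))
      f$importance$mean_delta_error[7]
    }, numeric(1))
    sd(imps)
  }, numeric(1))
  expect_true(sd_at[1] > sd_at[2] && sd_at[2] > sd_at[3])
})

test_that("forest agrees with an established implementation on planted data", {
  skip_if_not_installed("ranger")
  withr::with_seed(8, {
    X <- matrix(rnorm(80 * 40), 80)
    colnames(X) <- paste0("f", 1:40)
    y <- 2 * X[, 5] + rnorm(80, 0, 0.6)
  })
  ours <- fit_forest(X, y, forest_config(n_trees = 1500, mtry = 13, seed = 1))
  rf <- ranger::ranger(x = X, y = y, num.trees = 1500, mtry = 13,
                       min.node.size = 5, seed = 1, num.threads = 1,
                       importance = "permutation")
  ranger_nse <- nse(y, rf$predictions)
  expect_gt(ours$nse, 0.3)
  expect_gt(ranger_nse, 0.3)
  expect_lt(abs(ours$nse - ranger_nse), 0.15)
  expect_identical(
    ours$importance$feature[which.max(ours$importance$importance)],
    names(which.max(ranger::importance(rf)))
  )
})

test_that("forest input validation catches the documented failure modes", {
  d <- planted_data(n = 20, p = 5, seed = 9)
  expect_error(
    fit_forest(d$X, d$y, forest_config(n_trees = 1, mtry = 2, seed = 1),
               importance = FALSE),
    "increase n_trees"
  )
  expect_error(fit_forest(d$X[1:5, ], d$y[1:5], forest_config()),
               "at least 10 subjects")
  expect_error(fit_forest(d$X, d$y, forest_config(mtry = 6)),
               "exceeds the number of features")
  bad <- d$X
  bad[2, 2] <- NA
  expect_error(fit_forest(bad, d$y, forest_config(mtry = 3)),
               "missing values")
})

test_that("tidy and glance summarize the fitted forest", {
  d <- planted_data(seed = 10)
  colnames(d$X) <- feature_names(tiny_montage(1))
  f <- fit_forest(d$X, d$y, forest_config(n_trees = 100, mtry = 7, seed = 2))
  td <- tidy(f)
  expect_true(all(c("feature", "importance", "channel", "freq") %in%
                    names(td)))
  expect_equal(nrow(td), 50)
  gl <- glance(f)
  expect_equal(gl$nse, f$nse)
  expect_equal(gl$n_trees, 100)
})
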