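#' Permutation-null significance test for forest performance
#'
#' Shuffles the outcome vector `n_permutations` times (features untouched),
#' refits the forest with the same configuration on each shuffled outcome, and
#' records the OOB [nse()] of every refit, giving a null distribution of the
#' fit statistic under "no feature-outcome association". The p-value is the
#' frequency of null models that perform equal to or better than the observed
#' model.
#'
#' With the plug-in convention `p = count / n_permutations` (default), a model
#' never reached by any permutation reports p = 0, which in text should be
#' read as p < 1/n_permutations; the conservative `(count + 1) /
#' (n_permutations + 1)` convention is available via `p_method = "add-one"`.
#'
#' @inheritParams fit_forest
#' @param n_permutations Number of outcome shuffles (reference analysis:
#'   2000, giving a p resolution of 1/2000 = 5e-4).
#' @param seed Seed for the shuffles and per-permutation forest seeds
#'   (defaults to `config$seed`).
#' @param p_method `"plug-in"` (count/N) or `"add-one"` ((count+1)/(N+1)).
#' @param forest Optionally a prefitted `spectral_forest` for the observed
#'   outcome (must use the same `config`); avoids one refit.
#' @return A `permutation_null` object: `observed_nse`, `null_nse` (length
#'   `n_permutations`), `count_at_or_above`, `p_value`, `n_permutations`,
#'   `seed`. Supports [tidy()], [glance()], [ggplot2::autoplot()].
#' @export
permutation_test <- function(features, outcome, config = forest_config(),
                             n_permutations = 2000, seed = config$seed,
                             p_method = c("plug-in", "add-one"),
                             forest = NULL) {
  p_method <- match.arg(p_method)
  n_permutations <- check_count(n_permutations, "n_permutations")
  X <- feature_matrix(features)
  outcome <- as.numeric(outcome)

  if (is.null(forest)) {
    forest <- fit_forest(X, outcome, config, importance = FALSE)
  }
  observed <- forest$nse

  n <- length(outcome)
  null_nse <- numeric(n_permutations)
  local_seed(seed, {
    perm_seeds <- sample.int(2147483646L, n_permutations, replace = TRUE)
    for (b in seq_len(n_permutations)) {
      yb <- outcome[sample.int(n)]
      cfg <- config
      cfg$seed <- perm_seeds[b]
      fit <- tryCatch(
        fit_forest(X, yb, cfg, importance = FALSE),
        error = function(e) {
          abort(sprintf("permutation %d failed: %s", b, conditionMessage(e)))
        }
      )
      null_nse[b] <- fit$nse
    }
  })

  count <- sum(null_nse >= observed)
  structure(
    list(
      observed_nse = observed,
      null_nse = null_nse,
      count_at_or_above = count,
      p_value = permutation_p(count, n_permutations, p_method),
      n_permutations = n_permutations,
      p_method = p_method,
      seed = seed
    ),
    class = "permutation_null"
  )
}

#' Permutation p-value from a null-exceedance count
#'
#' @param count_at_or_above Number of null statistics at or above the
#'   observed one.
#' @param n_permutations Total number of permutations (> 0).
#' @param method See [permutation_test()].
#' @return A fraction in \[0, 1\].
#' @examples
#' permutation_p(11, 2000) # 0.0055
#' permutation_p(13, 2000) # 0.0065
#' permutation_p(14, 2000) # 0.007
#' @export
permutation_p <- function(count_at_or_above, n_permutations,
                          method = c("plug-in", "add-one")) {
  method <- match.arg(method)
  n_permutations <- check_count(n_permutations, "n_permutations")
  count_at_or_above <- check_count(count_at_or_above, "count_at_or_above",
                                   min = 0L)
  if (count_at_or_above > n_permutations) {
    abort("`count_at_or_above` cannot exceed `n_permutations`")
  }
  if (method == "plug-in") {
    count_at_or_above / n_permutations
  } else {
    (count_at_or_above + 1) / (n_permutations + 1)
  }
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error level.
#' @param n_tests Number of tests corrected for.
#' @return `alpha / n_tests`. With `alpha = 0.05` over seven cognitive tests
#'   this is 0.00714 (3 s.f.).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 7) {
  alpha <- check_number(alpha, "alpha", min = 0)
  n_tests <- check_count(n_tests, "n_tests")
  alpha / n_tests
}

#' @export
print.permutation_null <- function(x, ...) {
  ptxt <- if (x$count_at_or_above == 0 && x$p_method == "plug-in") {
    sprintf("< %g", 1 / x$n_permutations)
  } else {
    format(x$p_value)
  }
  cat(sprintf(
    "<permutation_null>  observed NSE %.4f, %d/%d null values >= observed, p = %s\n",
    x$observed_nse, x$count_at_or_above, x$n_permutations, ptxt
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.permutation_null <- function(x, ...) {
  tibble(permutation = seq_len(x$n_permutations), null_nse = x$null_nse)
}

#' @exportS3Method generics::glance
glance.permutation_null <- function(x, ...) {
  tibble(
    observed_nse = x$observed_nse,
    p_value = x$p_value,
    count_at_or_above = x$count_at_or_above,
    n_permutations = x$n_permutations,
    null_mean = mean(x$null_nse),
    null_sd = sd(x$null_nse)
  )
}

#' Electrode-averaged importance profile by frequency
#'
#' Averages per-feature importance across channels within each 1-Hz bin,
#' producing the frequency profile in which predictive peaks are sought.
#'
#' @param importance A `spectral_forest` (fitted with importance) or a tibble
#'   with columns `feature`, `importance` following the `"<channel>_<freq>Hz"`
#'   naming.
#' @return Tibble with columns `freq`, `importance` (one row per bin,
#'   ascending).
#' @export
frequency_profile <- function(importance) {
  imp <- importance_table(importance)
  info <- parse_features(imp$feature)
  if (anyNA(info$freq)) {
    abort("importance has features outside the <channel>_<freq>Hz convention")
  }
  grid <- table(info$channel, info$freq)
  if (any(grid != 1)) {
    abort("importance is missing (channel, frequency) cells")
  }
  dplyr::summarise(
    dplyr::group_by(
      tibble(freq = info$freq, importance = imp$importance), .data$freq
    ),
    importance = mean(.data$importance), .groups = "drop"
  )
}

importance_table <- function(importance) {
  if (inherits(importance, "spectral_forest")) {
    if (is.null(importance$importance)) {
      abort("forest was fitted with importance = FALSE")
    }
    importance <- importance$importance
  }
  if (!is.data.frame(importance) ||
      !all(c("feature", "importance") %in% names(importance))) {
    abort("`importance` must have columns feature and importance")
  }
  importance
}

#' Select importance peaks in a frequency profile
#'
#' A frequency is a peak when its profile value strictly exceeds both
#' neighbours (the single neighbour at the profile edges) and lies more than
#' `threshold_sd` sample standard deviations above the profile mean.
#'
#' @param profile Output of [frequency_profile()] (or a plain numeric vector,
#'   taken to be at 1..length Hz).
#' @param threshold_sd Height criterion in SD units (default 1).
#' @return Numeric vector of peak frequencies, ascending (possibly empty).
#' @export
find_peaks <- function(profile, threshold_sd = 1) {
  if (is.numeric(profile)) {
    profile <- tibble(freq = as.numeric(seq_along(profile)),
                      importance = as.numeric(profile))
  }
  stopifnot(all(c("freq", "importance") %in% names(profile)))
  v <- profile$importance[order(profile$freq)]
  f <- sort(profile$freq)
  if (any(!is.finite(v))) abort("profile contains non-finite values")
  k <- length(v)
  if (k < 2) return(numeric(0))
  cut <- mean(v) + threshold_sd * sd(v)
  is_peak <- logical(k)
  for (i in seq_len(k)) {
    left_ok <- i == 1 || v[i] > v[i - 1]
    right_ok <- i == k || v[i] > v[i + 1]
    is_peak[i] <- left_ok && right_ok && v[i] > cut
  }
  f[is_peak]
}

#' Importance topography at one frequency
#'
#' @param importance As in [frequency_profile()].
#' @param freq Frequency bin (Hz).
#' @param montage Montage tibble for scalp coordinates.
#' @return Tibble `channel`, `x`, `y`, `importance` (one row per channel).
#' @export
importance_topography <- function(importance, freq,
                                  montage = montage_1010()) {
  imp <- importance_table(importance)
  info <- parse_features(imp$feature)
  sel <- !is.na(info$freq) & info$freq == freq
  if (!any(sel)) abort(sprintf("no features at %g Hz", freq))
  montage <- as_montage(montage)
  out <- dplyr::left_join(
    tibble(channel = info$channel[sel], importance = imp$importance[sel]),
    montage, by = "channel"
  )
  out[c("channel", "x", "y", "importance")]
}

#' Signed univariate effects at the most important channels of a peak
#'
#' For a selected peak frequency, takes the `k_top` channels with highest
#' importance at that frequency and fits, per channel, a univariate linear
#' regression of the outcome on that channel's (residualized) power with both
#' variables z-scored. The signed standardized coefficient gives the
#' direction of effect (e.g. more power, fewer errors).
#'
#' @inheritParams fit_forest
#' @param importance As in [frequency_profile()]; typically the fitted
#'   forest whose peak is being followed up.
#' @param freq Peak frequency (Hz).
#' @param k_top Number of top channels (default 3).
#' @return Tibble `freq`, `channel`, `importance`, `beta`, `p_value`, ordered
#'   by decreasing importance.
#' @export
direction_of_effect <- function(features, outcome, importance, freq,
                                k_top = 3) {
  k_top <- check_count(k_top, "k_top")
  imp <- importance_table(importance)
  info <- parse_features(imp$feature)
  sel <- which(!is.na(info$freq) & info$freq == freq)
  if (length(sel) == 0) abort(sprintf("no features at %g Hz", freq))
  if (k_top > length(sel)) {
    abort(sprintf("k_top (%d) exceeds the %d channels at %g Hz", k_top,
                  length(sel), freq))
  }
  top <- sel[order(-imp$importance[sel])][seq_len(k_top)]

  X <- feature_matrix(features)
  y <- scale(as.numeric(outcome))[, 1]
  purrr::map_dfr(top, function(i) {
    fname <- imp$feature[i]
    if (!fname %in% colnames(X)) {
      abort(sprintf("feature %s absent from `features`", fname))
    }
    x <- scale(X[, fname])[, 1]
    fit <- summary(stats::lm(y ~ x))
    tibble(
      freq = freq,
      channel = info$channel[i],
      importance = imp$importance[i],
      beta = fit$coefficients["x", "Estimate"],
      p_value = fit$coefficients["x", "Pr(>|t|)"]
    )
  })
}
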