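#' Welch's heteroscedasticity-robust one-way ANOVA across diagnostic groups
#'
#' Tests whether (residualized) cognitive scores differ among diagnostic
#' groups without assuming equal group variances, including only groups with
#' more than `min_group_n` members (strict inequality: a group with exactly
#' `min_group_n` subjects is excluded). Degrees of freedom follow the
#' Welch-Satterthwaite approximation, so `df2` is fractional.
#'
#' Scores are expected to be residualized on age and gender beforehand (see
#' [residualize_scores()]); the test itself does not adjust for covariates.
#'
#' @param data Data frame of per-subject records.
#' @param score,group Column names (strings) of the numeric score and the
#'   group label.
#' @param min_group_n Group-size threshold; groups with `n > min_group_n`
#'   are included.
#' @return One-row tibble: `f`, `df1`, `df2`, `p_value`, `n_groups`,
#'   `groups` (comma-separated labels), `n_total`.
#' @export
welch_anova <- function(data, score = "score", group = "diagnosis",
                        min_group_n = 10) {
  if (!score %in% names(data)) abort(sprintf("column '%s' not found", score))
  if (!group %in% names(data)) abort(sprintf("column '%s' not found", group))
  y <- as.numeric(data[[score]])
  g <- as.character(data[[group]])
  ok <- complete.cases(y, g)
  y <- y[ok]
  g <- g[ok]
  sizes <- table(g)
  keep <- names(sizes)[sizes > min_group_n]
  if (length(keep) < 2) {
    abort(sprintf("fewer than 2 groups have n > %d", min_group_n))
  }
  sel <- g %in% keep
  y <- y[sel]
  g <- factor(g[sel], levels = keep)
  if (any(tapply(y, g, var) == 0)) {
    abort("a group has zero within-group variance")
  }
  ft <- oneway.test(y ~ g, var.equal = FALSE)
  tibble(
    f = unname(ft$statistic),
    df1 = unname(ft$parameter["num df"]),
    df2 = unname(ft$parameter["denom df"]),
    p_value = unname(ft$p.value),
    n_groups = length(keep),
    groups = paste(keep, collapse = ","),
    n_total = length(y)
  )
}

#' Pearson correlations between cognitive scores and symptom dimensions
#'
#' Computes, for every (outcome, dimension) pair, the Pearson correlation
#' over pairwise-complete observations with its two-sided p-value. No
#' multiple-testing correction is applied to this grid (raw p-values are
#' reported, as in the reference analysis).
#'
#' @param data Data frame of per-subject records.
#' @param outcomes Character vector of outcome column names.
#' @param dimensions Character vector of symptom-dimension column names
#'   (defaults to the five packaged dimension names).
#' @return Tibble `outcome`, `dimension`, `r`, `p_value`, `n`; `r` is NA with
#'   a warning when a vector is constant.
#' @export
symptom_correlations <- function(data, outcomes,
                                 dimensions = symptom_dimension_names()) {
  missing_cols <- setdiff(c(outcomes, dimensions), names(data))
  if (length(missing_cols)) {
    abort(sprintf("column(s) not found: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(outcome = outcomes, dimension = dimensions)
  purrr::pmap_dfr(grid, function(outcome, dimension) {
    x <- as.numeric(data[[outcome]])
    y <- as.numeric(data[[dimension]])
    ok <- complete.cases(x, y)
    x <- x[ok]
    y <- y[ok]
    if (length(x) < 3) abort("fewer than 3 pairwise-complete observations")
    if (var(x) == 0 || var(y) == 0) {
      warn(sprintf("constant vector in (%s, %s): correlation undefined",
                   outcome, dimension))
      return(tibble(outcome = outcome, dimension = dimension, r = NA_real_,
                    p_value = NA_real_, n = length(x)))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(outcome = outcome, dimension = dimension,
           r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
  })
}

#' Diagnosis-prediction control forests
#'
#' Fits one regression forest per diagnosis label on a one-vs-rest 0/1
#' indicator (a regression rather than classification model, so prediction
#' values are graded), with OOB NSE and a permutation p-value per label. On
#' cohorts whose labels are independent of the EEG -- the synthetic default --
#' no model should beat chance; a significant model here would suggest the
#' cognition-EEG association is secondary to diagnosis-EEG structure.
#'
#' @inheritParams fit_forest
#' @param diagnosis Character/factor vector of diagnosis labels, one per
#'   subject.
#' @param n_permutations,seed,p_method Passed to [permutation_test()].
#' @param min_positive Labels with fewer positives are skipped with a
#'   warning.
#' @return Tibble `diagnosis`, `n_positive`, `nse`, `p_value`,
#'   `count_at_or_above`, one row per tested label.
#' @export
diagnosis_forests <- function(features, diagnosis, config = forest_config(),
                              n_permutations = 2000, seed = config$seed,
                              p_method = c("plug-in", "add-one"),
                              min_positive = 5) {
  p_method <- match.arg(p_method)
  X <- feature_matrix(features)
  diagnosis <- as.character(diagnosis)
  if (length(diagnosis) != nrow(X)) {
    abort("`diagnosis` must have one label per subject")
  }
  labels <- sort(unique(diagnosis))
  out <- list()
  for (k in seq_along(labels)) {
    lab <- labels[k]
    ind <- as.numeric(diagnosis == lab)
    if (sum(ind) < min_positive) {
      warn(sprintf("diagnosis '%s' skipped: only %d positive(s)", lab,
                   sum(ind)))
      next
    }
    pt <- permutation_test(X, ind, config, n_permutations,
                           seed = seed + k, p_method = p_method)
    out[[lab]] <- tibble(
      diagnosis = lab, n_positive = as.integer(sum(ind)),
      nse = pt$observed_nse, p_value = pt$p_value,
      count_at_or_above = pt$count_at_or_above
    )
  }
  if (!length(out)) abort("no diagnosis label had enough positives")
  dplyr::bind_rows(out)
}
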