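#' Nash-Sutcliffe efficiency
#'
#' Model-fit statistic between observed values \eqn{Y_m} and predictions
#' \eqn{Y_p}:
#' \deqn{NSE = 1 - \sum (Y_m - Y_p)^2 / \sum (Y_m - \bar Y)^2}
#' NSE ranges over \eqn{(-\infty, 1]}: 1 for perfect prediction, 0 for a
#' model no better than the observed mean, negative for worse than the mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A single number.
#' @examples
#' nse(c(1, 2, 3, 4), c(1, 2, 3, 4)) # 1
#' nse(c(1, 2, 3, 4), rep(2.5, 4))   # 0
#' @export
nse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length")
  }
  if (length(observed) < 2) abort("need at least 2 observations")
  if (anyNA(observed) || anyNA(predicted) ||
      any(!is.finite(observed)) || any(!is.finite(predicted))) {
    abort("non-finite values in `observed` or `predicted`")
  }
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) {
    abort("`observed` is constant: NSE undefined (zero denominator)")
  }
  1 - sum((observed - predicted)^2) / denom
}

#' Random-forest configuration
#'
#' Hyperparameters for the bagged regression-tree ensemble. The reference
#' analysis configuration is 20,000 trees with 12 predictors sampled at each
#' split (`preset = "paper"`); the default desk configuration uses 2,000
#' trees, which is cheap and close to converged for the OOB fit statistic
#' (importance estimates keep shrinking in variance up to far larger
#' ensembles; see the vignette).
#'
#' @param n_trees Number of trees.
#' @param mtry Number of predictors sampled (without replacement) at each
#'   split.
#' @param min_leaf Minimum observations per leaf; splits that would produce a
#'   smaller child are not considered.
#' @param seed Integer seed for the forest's internal deterministic RNG.
#' @param importance `"per-tree-sd"` (mean increase in OOB squared error when
#'   the predictor is permuted, divided by its standard deviation across
#'   trees) or `"raw"` (the mean increase itself).
#' @param preset `"desk"` (defaults as given) or `"paper"`
#'   (20,000 trees, mtry 12).
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_trees = 2000, mtry = 12, min_leaf = 5, seed = 1,
                          importance = c("per-tree-sd", "raw"),
                          preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    if (missing(n_trees)) n_trees <- 20000
    if (missing(mtry)) mtry <- 12
  }
  structure(
    list(
      n_trees = check_count(n_trees, "n_trees"),
      mtry = check_count(mtry, "mtry"),
      min_leaf = check_count(min_leaf, "min_leaf"),
      seed = check_count(seed, "seed", min = 0L),
      importance = match.arg(importance),
      preset = preset
    ),
    class = "forest_config"
  )
}

#' Fit a random forest with out-of-bag evaluation
#'
#' Grows `config$n_trees` CART-style regression trees (variance-reduction
#' splits, `config$mtry` candidate predictors per split, bootstrap of n
#' subjects with replacement per tree). Each subject's prediction is the mean
#' over the trees whose bootstrap excluded that subject ("out-of-bag"), and
#' the [nse()] of these OOB predictions is the generalization estimate.
#' Permutation importance is measured per tree by shuffling each used
#' predictor among the tree's OOB subjects and recording the increase in OOB
#' mean squared error.
#'
#' Outcomes enter the forest raw: in this pipeline only the power features
#' (and, separately, the scores used in group tests) are residualized on age
#' and gender, not the forest's target.
#'
#' @param features Feature table (tibble with `subject_id` + numeric feature
#'   columns) or numeric matrix, one row per subject.
#' @param outcome Numeric outcome vector, one value per subject.
#' @param config A [forest_config()].
#' @param importance Compute permutation importance (default TRUE; skipping it
#'   does not change the trees or OOB predictions).
#' @param keep_forest Keep the per-tree node tables in the result (for
#'   inspection; off by default).
#' @return A `spectral_forest` object with elements `nse`, `oob_predictions`,
#'   `observed`, `oob_counts`, `importance` (tibble or NULL), `config`.
#'   Supports [tidy()], [glance()] and `print()`.
#' @export
fit_forest <- function(features, outcome, config = forest_config(),
                       importance = TRUE, keep_forest = FALSE) {
  X <- feature_matrix(features)
  n <- nrow(X)
  p <- ncol(X)
  outcome <- as.numeric(outcome)
  if (length(outcome) != n) abort("`outcome` must have one value per subject")
  if (anyNA(X) || any(!is.finite(X))) abort("missing values in `features`")
  if (anyNA(outcome) || any(!is.finite(outcome))) {
    abort("missing values in `outcome`")
  }
  if (n < 10) abort("random forest requires at least 10 subjects")
  if (config$mtry > p) {
    abort(sprintf("mtry (%d) exceeds the number of features (%d)",
                  config$mtry, p))
  }

  raw <- .rf_fit_cpp(X, outcome, config$n_trees, config$mtry,
                     config$min_leaf, as.numeric(config$seed),
                     importance, keep_forest)
  if (any(raw$oob_count == 0)) {
    abort(paste0(
      sum(raw$oob_count == 0),
      " subject(s) were out-of-bag in zero trees; increase n_trees"
    ))
  }
  oob_pred <- raw$oob_sum / raw$oob_count

  imp <- NULL
  if (importance) {
    scaled <- if (config$importance == "per-tree-sd") {
      ifelse(raw$importance_sd > 0,
             raw$importance_mean / raw$importance_sd, 0)
    } else {
      raw$importance_mean
    }
    nm <- colnames(X) %||% sprintf("x%d", seq_len(p))
    const_oob <- raw$importance_sd == 0 & raw$importance_mean == 0 &
      apply(X, 2, function(v) var(v) == 0)
    if (any(const_oob)) {
      warn(sprintf("%d constant feature(s) have importance 0",
                   sum(const_oob)))
    }
    imp <- tibble(
      feature = nm,
      importance = as.numeric(scaled),
      mean_delta_error = as.numeric(raw$importance_mean),
      sd_delta_error = as.numeric(raw$importance_sd)
    )
  }

  structure(
    list(
      nse = nse(outcome, oob_pred),
      oob_predictions = as.numeric(oob_pred),
      observed = outcome,
      oob_counts = as.integer(raw$oob_count),
      importance = imp,
      config = config,
      n_subjects = n,
      n_features = p,
      trees = if (keep_forest) raw$trees
    ),
    class = "spectral_forest"
  )
}

#' @export
print.spectral_forest <- function(x, ...) {
  cat(sprintf(
    "<spectral_forest>  %d subjects, %d features, %d trees (mtry %d)\n",
    x$n_subjects, x$n_features, x$config$n_trees, x$config$mtry
  ))
  cat(sprintf("  OOB NSE: %.4f   (min trees OOB per subject: %d)\n",
              x$nse, min(x$oob_counts)))
  if (!is.null(x$importance)) {
    top <- x$importance$feature[which.max(x$importance$importance)]
    cat(sprintf("  top importance: %s\n", top))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spectral_forest <- function(x, ...) {
  if (is.null(x$importance)) {
    abort("forest was fitted with importance = FALSE")
  }
  dplyr::left_join(x$importance, parse_features(x$importance$feature),
                   by = "feature")
}

#' @exportS3Method generics::glance
glance.spectral_forest <- function(x, ...) {
  tibble(
    nse = x$nse,
    n_subjects = x$n_subjects,
    n_features = x$n_features,
    n_trees = x$config$n_trees,
    mtry = x$config$mtry,
    min_leaf = x$config$min_leaf,
    min_oob_count = min(x$oob_counts),
    seed = x$config$seed
  )
}
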