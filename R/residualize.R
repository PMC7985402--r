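#' Residualize spectral features on age and gender
#'
#' Fits, per feature column, an ordinary least squares model on
#' `[1, age, gender]` across the whole sample and replaces each column with
#' its residuals, so that downstream models see power corrected for the two
#' covariates. The fitted coefficients are returned so that new subjects can
#' be residualized with frozen coefficients via [residualize_apply()].
#'
#' A covariate that is constant across the sample (e.g. a single-gender
#' cohort) carries no information and is dropped from the design with a
#' warning. Gender is expected as a 0/1 indicator; which level is coded 1
#' only flips the sign of the gender slope and leaves residuals unchanged.
#'
#' @param features Feature table (tibble with `subject_id` + numeric columns)
#'   or numeric matrix.
#' @param age,gender Numeric covariate vectors, one value per subject.
#' @return A list with `features` (residualized table, same shape as the
#'   input) and `model` (a `covariate_model`: coefficient matrix with one
#'   column per feature and the retained regressor names).
#' @examples
#' f <- tibble::tibble(subject_id = letters[1:6],
#'                     a = c(1, 2, 3, 4, 5, 6) * 2)
#' out <- fit_residualize(f, age = c(1, 2, 3, 4, 5, 6), gender = rep(0:1, 3))
#' max(abs(out$features$a)) # ~0: the column was an exact function of age
#' @export
fit_residualize <- function(features, age, gender) {
  Y <- feature_matrix(features)
  n <- nrow(Y)
  if (n < 3) abort("residualization needs at least 3 subjects")
  if (length(age) != n || length(gender) != n) {
    abort("`age` and `gender` must have one value per subject")
  }
  if (anyNA(age) || anyNA(gender)) abort("missing covariate values")

  X <- cbind(intercept = 1, age = as.numeric(age), gender = as.numeric(gender))
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) {
    var(v) > 0
  }))
  if (!all(keep)) {
    dropped <- colnames(X)[!keep]
    warn(sprintf("constant covariate dropped from design: %s",
                 paste(dropped, collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  fit <- lm.fit(X, Y)
  res <- Y - X %*% fit$coefficients
  model <- structure(
    list(coefficients = fit$coefficients, regressors = colnames(X)),
    class = "covariate_model"
  )
  list(features = rebuild_features(features, res), model = model)
}

#' @rdname fit_residualize
#' @param model A `covariate_model` from [fit_residualize()].
#' @export
residualize_apply <- function(model, features, age, gender) {
  stopifnot(inherits(model, "covariate_model"))
  Y <- feature_matrix(features)
  X <- cbind(intercept = 1, age = as.numeric(age),
             gender = as.numeric(gender))[, model$regressors, drop = FALSE]
  res <- Y - X %*% model$coefficients
  rebuild_features(features, res)
}

#' Residualize a score vector on age and gender
#'
#' Single-column counterpart of [fit_residualize()], used to correct
#' cognitive scores before the group-difference tests.
#'
#' @inheritParams fit_residualize
#' @param scores Numeric outcome vector.
#' @return Numeric vector of residuals.
#' @export
residualize_scores <- function(scores, age, gender) {
  out <- fit_residualize(matrix(as.numeric(scores), ncol = 1,
                                dimnames = list(NULL, "score")),
                         age, gender)
  as.numeric(out$features)
}

# put a residual matrix back into the container shape the caller supplied
rebuild_features <- function(features, res) {
  if (is.matrix(features)) return(res)
  out <- features
  out[colnames(res)] <- as.data.frame(res)
  out
}
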