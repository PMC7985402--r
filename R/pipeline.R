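#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Exactly one of
#' `feature_table` / `recordings` must be supplied (a path or an in-memory
#' object). The `"paper"` preset pins the reference analysis parameters:
#' 20,000 trees, 12 predictors sampled, 2,000 permutations, alpha 0.05 over 7
#' tests; the `"desk"` preset (500 trees, 200 permutations) is a clearly
#' scaled-down configuration for interactive work and tests. Explicit
#' arguments override the preset.
#'
#' @param feature_table Path to a feature CSV (or a feature tibble).
#' @param recordings Path-free in-memory `eeg_recordings` object (time-domain
#'   input).
#' @param subject_table Path to the subject CSV (or a tibble): columns
#'   `subject_id`, `age`, `gender`, `diagnosis`, outcome columns, and
#'   optionally the five symptom-dimension columns.
#' @param output_dir Directory for report files.
#' @param outcomes Outcome column names; default: every non-reserved,
#'   non-symptom column of the subject table.
#' @param window_length,overlap Spectral parameters (time-domain input only).
#' @param n_trees,mtry,min_leaf,forest_seed Forest parameters.
#' @param n_permutations Permutation count.
#' @param alpha,n_tests Familywise level and Bonferroni divisor (default
#'   `n_tests = length(outcomes)`).
#' @param preset `"desk"` or `"paper"`.
#' @param seed Master seed.
#' @param run_diagnosis_forests Also run the one-vs-rest diagnosis control
#'   forests (off by default; they cost one permutation test per label).
#' @param min_group_n Group-size threshold of the Welch ANOVA.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(feature_table = NULL, recordings = NULL,
                            subject_table, output_dir,
                            outcomes = NULL,
                            window_length = 512, overlap = 0.5,
                            n_trees = NULL, mtry = 12, min_leaf = 5,
                            forest_seed = NULL,
                            n_permutations = NULL,
                            alpha = 0.05, n_tests = NULL,
                            preset = c("desk", "paper"),
                            seed = 1,
                            run_diagnosis_forests = FALSE,
                            min_group_n = 10) {
  preset <- match.arg(preset)
  if (is.null(feature_table) == is.null(recordings)) {
    abort("supply exactly one of `feature_table` and `recordings`")
  }
  defaults <- switch(preset,
    paper = list(n_trees = 20000, n_permutations = 2000),
    desk = list(n_trees = 500, n_permutations = 200)
  )
  structure(
    list(
      feature_table = feature_table, recordings = recordings,
      subject_table = subject_table, output_dir = output_dir,
      outcomes = outcomes,
      window_length = window_length, overlap = overlap,
      n_trees = check_count(n_trees %||% defaults$n_trees, "n_trees"),
      mtry = check_count(mtry, "mtry"),
      min_leaf = check_count(min_leaf, "min_leaf"),
      forest_seed = forest_seed,
      n_permutations = check_count(n_permutations %||% defaults$n_permutations,
                                   "n_permutations"),
      alpha = check_number(alpha, "alpha", min = 0),
      n_tests = n_tests,
      preset = preset,
      seed = check_count(seed, "seed", min = 0L),
      run_diagnosis_forests = isTRUE(run_diagnosis_forests),
      min_group_n = check_count(min_group_n, "min_group_n", min = 0L)
    ),
    class = "pipeline_config"
  )
}

#' Read / write pipeline configurations as YAML
#'
#' The on-disk representation holds only plain values (paths, numbers), so a
#' config written to YAML and read back is identical; the run manifest embeds
#' the same representation, making any report reproducible from its manifest
#' alone.
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(config_as_plain(config), path)
  invisible(path)
}

config_as_plain <- function(config) {
  plain <- unclass(config)
  for (nm in c("feature_table", "recordings", "subject_table")) {
    if (!is.null(plain[[nm]]) && !is.character(plain[[nm]])) {
      abort(sprintf("`%s` must be a file path to serialize the config", nm))
    }
  }
  plain[!vapply(plain, is.null, logical(1))]
}

#' Feature-table CSV I/O
#'
#' The feature CSV has `subject_id` as first column and one column per
#' `"<channel>_<freq>Hz"` feature; a JSON sidecar (`<path>.json`) records the
#' spectral parameters and residualization status.
#'
#' @param features Feature tibble.
#' @param path CSV path.
#' @param sidecar Named list of metadata for the sidecar (window length,
#'   overlap, log base, residualized flag, ...).
#' @export
write_feature_table <- function(features, path, sidecar = list()) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  write.csv(features, path, row.names = FALSE)
  side <- c(list(log_base = "natural", n_features = ncol(features) - 1L),
            sidecar)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param required_features Optional feature names that must be present;
#'   a missing column is a validation error naming it.
#' @export
read_feature_table <- function(path, required_features = NULL) {
  df <- as_tibble(read.csv(path, check.names = FALSE))
  if (!"subject_id" %in% names(df)) {
    abort("feature table lacks a `subject_id` column")
  }
  df$subject_id <- as.character(df$subject_id)
  if (!is.null(required_features)) {
    missing_cols <- setdiff(required_features, names(df))
    if (length(missing_cols)) {
      abort(sprintf("feature table is missing column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    }
  }
  df
}

#' @rdname write_feature_table
#' @export
read_subject_table <- function(path) {
  df <- as_tibble(read.csv(path, check.names = FALSE))
  needed <- c("subject_id", "age", "gender")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    abort(sprintf("subject table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

reserved_subject_columns <- function() {
  c("subject_id", "age", "gender", "diagnosis")
}

#' Run the full analysis pipeline
#'
#' Executes, for every outcome column: feature extraction (if recordings were
#' supplied), residualization of the power features on age and gender, a
#' random forest with OOB NSE, the outcome-permutation significance test,
#' and -- for outcomes passing the Bonferroni threshold -- importance
#' frequency profiling, peak selection, topography export, and top-channel
#' direction-of-effect regressions. Follow-ups: Welch's ANOVA across
#' diagnostic groups on residualized scores of significant outcomes,
#' the symptom-dimension correlation grid, and (optionally) diagnosis
#' control forests.
#'
#' Every run writes to `output_dir`: `report_<outcome>.json`,
#' `importance_<outcome>.csv`, `topography_<outcome>_<freq>Hz.csv`,
#' `welch_anova.csv`, `symptom_correlations.csv`, `diagnosis_forests.csv`
#' (optional), a byte-stable `manifest.json` (effective parameters, seeds,
#' package version) and `timings.json`. Reruns with the same config and seed
#' produce byte-identical reports; only `timings.json` differs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`reports`,
#'   `followup`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()

  subjects <- if (is.character(config$subject_table)) {
    read_subject_table(config$subject_table)
  } else {
    as_tibble(config$subject_table)
  }

  if (!is.null(config$recordings)) {
    recs <- config$recordings
    features <- spectral_features(recs, window_length = config$window_length,
                                  overlap = config$overlap)
  } else {
    features <- if (is.character(config$feature_table)) {
      read_feature_table(config$feature_table)
    } else {
      as_tibble(config$feature_table)
    }
  }
  if (!identical(as.character(features$subject_id),
                 as.character(subjects$subject_id))) {
    features <- features[match(subjects$subject_id, features$subject_id), ]
    if (anyNA(features$subject_id)) {
      abort("feature and subject tables do not cover the same subjects")
    }
  }
  timings$load <- proc.time()[["elapsed"]] - t0

  sym <- intersect(symptom_dimension_names(), names(subjects))
  outcomes <- config$outcomes %||%
    setdiff(names(subjects)[vapply(subjects, is.numeric, logical(1))],
            c(reserved_subject_columns(), sym))
  if (!length(outcomes)) abort("no outcome columns found")
  n_tests <- config$n_tests %||% length(outcomes)
  threshold <- bonferroni_threshold(config$alpha, n_tests)

  t1 <- proc.time()[["elapsed"]]
  resid <- fit_residualize(features, subjects$age, subjects$gender)
  features_r <- resid$features
  timings$residualize <- proc.time()[["elapsed"]] - t1

  cfg <- forest_config(n_trees = config$n_trees, mtry = config$mtry,
                       min_leaf = config$min_leaf,
                       seed = config$forest_seed %||% config$seed)
  X <- feature_matrix(features_r)

  reports <- list()
  for (oc in outcomes) {
    t2 <- proc.time()[["elapsed"]]
    y <- as.numeric(subjects[[oc]])
    forest <- fit_forest(X, y, cfg, importance = TRUE)
    pt <- permutation_test(X, y, cfg, config$n_permutations,
                           seed = config$seed, forest = forest)
    significant <- pt$p_value < threshold

    peaks <- numeric(0)
    peak_tables <- list()
    effects <- NULL
    if (significant) {
      prof <- frequency_profile(forest)
      peaks <- find_peaks(prof)
      for (pk in peaks) {
        topo <- importance_topography(forest, pk)
        write.csv(topo,
                  file.path(config$output_dir,
                            sprintf("topography_%s_%dHz.csv", oc,
                                    as.integer(pk))),
                  row.names = FALSE)
        peak_tables[[as.character(pk)]] <- topo
      }
      if (length(peaks)) {
        n_ch <- length(unique(parse_features(forest$importance$feature)$channel))
        effects <- purrr::map_dfr(peaks, function(pk) {
          direction_of_effect(features_r, y, forest, pk,
                              k_top = min(3, n_ch))
        })
      }
    }

    write.csv(forest$importance,
              file.path(config$output_dir,
                        sprintf("importance_%s.csv", oc)),
              row.names = FALSE)
    report <- list(
      outcome = oc,
      nse = pt$observed_nse,
      p_value = pt$p_value,
      count_at_or_above = pt$count_at_or_above,
      n_permutations = pt$n_permutations,
      threshold = threshold,
      significant = significant,
      peaks = as.numeric(peaks),
      effects = if (!is.null(effects)) effects
    )
    jsonlite::write_json(
      report, file.path(config$output_dir, sprintf("report_%s.json", oc)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
    )
    reports[[oc]] <- c(report, list(forest = forest, permutation = pt))
    timings[[paste0("outcome_", oc)]] <- proc.time()[["elapsed"]] - t2
  }

  # follow-up statistics -----------------------------------------------------
  t3 <- proc.time()[["elapsed"]]
  followup <- list()
  sig_outcomes <- names(reports)[vapply(reports, `[[`, TRUE, "significant")]
  if ("diagnosis" %in% names(subjects) && length(sig_outcomes)) {
    wa <- purrr::map_dfr(sig_outcomes, function(oc) {
      df <- subjects
      df$.resid_score <- residualize_scores(df[[oc]], df$age, df$gender)
      res <- tryCatch(
        welch_anova(df, ".resid_score", "diagnosis",
                    min_group_n = config$min_group_n),
        error = function(e) {
          warn(sprintf("Welch ANOVA skipped for %s: %s", oc,
                       conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(res)) dplyr::bind_cols(tibble(outcome = oc), res)
    })
    if (nrow(wa %||% tibble())) {
      write.csv(wa, file.path(config$output_dir, "welch_anova.csv"),
                row.names = FALSE)
      followup$welch_anova <- wa
    }
  }
  if (length(sym) == 5) {
    sc <- symptom_correlations(subjects, outcomes, sym)
    write.csv(sc, file.path(config$output_dir, "symptom_correlations.csv"),
              row.names = FALSE)
    followup$symptom_correlations <- sc
  }
  if (config$run_diagnosis_forests && "diagnosis" %in% names(subjects)) {
    dfst <- diagnosis_forests(X, subjects$diagnosis, cfg,
                              config$n_permutations, seed = config$seed)
    write.csv(dfst, file.path(config$output_dir, "diagnosis_forests.csv"),
              row.names = FALSE)
    followup$diagnosis_forests <- dfst
  }
  timings$followup <- proc.time()[["elapsed"]] - t3

  manifest <- list(
    package = "spectralforest",
    version = as.character(packageVersion("spectralforest")),
    config = tryCatch(config_as_plain(config), error = function(e) {
      plain <- unclass(config)
      plain$feature_table <- plain$recordings <- plain$subject_table <- NULL
      c(plain[!vapply(plain, is.null, logical(1))],
        list(inputs = "in-memory"))
    }),
    outcomes = outcomes,
    n_tests = n_tests,
    threshold = threshold,
    forest_seed = cfg$seed
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  timings$total <- proc.time()[["elapsed"]] - t0
  jsonlite::write_json(timings,
                       file.path(config$output_dir, "timings.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(reports = reports, followup = followup, manifest = manifest))
}
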