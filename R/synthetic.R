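#' Specify a band-limited oscillation for synthetic EEG
#'
#' An oscillator is a rhythmic component (e.g. occipital alpha) with a centre
#' frequency, a bandwidth, a between-subject distribution of band log power,
#' and a scalp topography of weights in \[0, 1\]. Each synthetic subject draws
#' a latent band log power `L ~ N(mean_log_power, between_subject_sd^2)`; the
#' oscillator adds `topography[ch] * bump(f) * L` to the subject's log power
#' surface, where `bump` is a Gaussian profile of width `bandwidth / 2`
#' centred on `center_frequency`.
#'
#' @param name Oscillator label, referenced by [effect_spec()].
#' @param center_frequency Centre frequency in Hz (1--50).
#' @param bandwidth Full width of the spectral bump in Hz (> 0).
#' @param mean_log_power,between_subject_sd Latent band log power
#'   distribution (log uV^2 units).
#' @param topography Named numeric vector of per-channel weights in \[0, 1\],
#'   one entry per montage channel (see [topo_gaussian()]).
#' @return An `oscillator_spec` list.
#' @export
oscillator_spec <- function(name, center_frequency, bandwidth = 2,
                            mean_log_power = 2, between_subject_sd = 0.5,
                            topography) {
  if (!is.character(name) || length(name) != 1) {
    abort("oscillator `name` must be a single string")
  }
  center_frequency <- check_number(center_frequency, "center_frequency")
  if (center_frequency < 1 || center_frequency > 50) {
    abort("`center_frequency` must lie in [1, 50] Hz")
  }
  bandwidth <- check_number(bandwidth, "bandwidth")
  if (bandwidth <= 0) abort("`bandwidth` must be > 0")
  between_subject_sd <- check_number(between_subject_sd,
                                     "between_subject_sd", min = 0)
  if (is.null(names(topography)) || anyNA(topography) ||
      any(topography < 0 | topography > 1)) {
    abort("`topography` must be a named vector with weights in [0, 1]")
  }
  structure(
    list(name = name, center_frequency = center_frequency,
         bandwidth = bandwidth, mean_log_power = mean_log_power,
         between_subject_sd = between_subject_sd, topography = topography),
    class = "oscillator_spec"
  )
}

#' Gaussian scalp topography centred on a channel
#'
#' Convenience builder of oscillator topographies: weight
#' `exp(-d^2 / (2 width^2))` where `d` is the distance to `center` in the
#' montage's schematic coordinates; the centre channel has weight 1.
#'
#' @param montage Montage tibble.
#' @param center Channel name the topography peaks at.
#' @param width Spatial scale in montage units (head radius ~ 1).
#' @return Named numeric vector over all montage channels.
#' @export
topo_gaussian <- function(montage = montage_1010(), center, width = 0.5) {
  montage <- as_montage(montage)
  i <- match(center, montage$channel)
  if (is.na(i)) abort(sprintf("channel %s not in montage", center))
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  setNames(exp(-d2 / (2 * width^2)), montage$channel)
}

#' Specify a planted outcome-oscillator coupling
#'
#' Encodes the ground truth of the synthetic cohort: the named outcome equals
#' the sum over its couplings of `slope * L_oscillator` plus Gaussian noise
#' with standard deviation `noise_sd`. The sign of `slope` is the planted
#' direction of effect that the pipeline's univariate regressions should
#' recover.
#'
#' @param outcome Outcome (cognitive score) name.
#' @param oscillator Name of an oscillator present in the cohort spec.
#' @param slope Outcome units per log-power unit.
#' @param noise_sd Outcome noise SD (>= 0).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(outcome, oscillator, slope, noise_sd = 1) {
  if (!is.character(outcome) || length(outcome) != 1) {
    abort("`outcome` must be a single string")
  }
  if (!is.character(oscillator) || length(oscillator) != 1) {
    abort("`oscillator` must be a single string")
  }
  slope <- check_number(slope, "slope")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  structure(
    list(outcome = outcome, oscillator = oscillator, slope = slope,
         noise_sd = noise_sd),
    class = "effect_spec"
  )
}

#' Specify a synthetic cohort
#'
#' Collects everything needed to generate a synthetic clinical EEG cohort:
#' recording geometry, a 1/f spectral background, oscillators, planted
#' outcome couplings, covariate effects of age and gender on power, and
#' diagnosis labels drawn independently of the EEG (so diagnosis-prediction
#' forests have no signal to find, by construction). Defaults mimic the
#' reference cohort: age uniform with mean 38.6 and SD 15.0 years, 38.4%
#' male, seven diagnostic groups with the reference group proportions, and
#' five independent standard-normal symptom-dimension scores.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param montage Montage tibble; defaults to the packaged 64-channel 10/10
#'   set. `n_channels` may be given instead to take the first channels of the
#'   default montage.
#' @param n_channels Optional channel count (<= 64) when `montage` is not
#'   supplied.
#' @param sample_rate Sampling rate in Hz (time-domain path).
#' @param duration Recording length in seconds; `duration * sample_rate` must
#'   be a whole number of samples.
#' @param noise_exponent 1/f slope of the background: background log power
#'   falls as `-noise_exponent * log(f)`.
#' @param background_level Background log power (log uV^2) in the 1 Hz bin.
#' @param oscillators List of [oscillator_spec()]s.
#' @param couplings List of [effect_spec()]s; every referenced oscillator must
#'   be present in `oscillators`.
#' @param null_outcomes Names of additional outcomes that are pure N(0, 1)
#'   noise, independent of the EEG.
#' @param age_range Uniform age range in years (default gives mean 38.6,
#'   SD 15.0).
#' @param prop_male Probability of gender indicator 1 (male).
#' @param age_slope,gender_slope Covariate effect on log power, either a
#'   scalar (all bins) or a length-50 vector (per bin); units log-power per
#'   year / per indicator unit. Age is centred at the range midpoint.
#' @param measurement_sd Per-feature log-power measurement noise SD
#'   (feature-level path).
#' @param outcome_floor Names of outcomes clipped at 0 (error-count-like
#'   scores).
#' @param group_labels,group_probs Diagnosis labels and sampling proportions.
#' @param seed Integer seed; all generation is reproducible from it.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects,
                        montage = NULL,
                        n_channels = 64,
                        sample_rate = 512,
                        duration = 300,
                        noise_exponent = 1,
                        background_level = log(20),
                        oscillators = list(),
                        couplings = list(),
                        null_outcomes = character(),
                        age_range = c(12.6, 64.6),
                        prop_male = 0.384,
                        age_slope = 0,
                        gender_slope = 0,
                        measurement_sd = 0.4,
                        outcome_floor = character(),
                        group_labels = c("MDD", "BP", "PSY", "OCD", "GAD",
                                         "ASD", "ID-NOS"),
                        group_probs = c(34, 4, 15, 49, 9, 4, 101) / 216,
                        seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  if (is.null(montage)) {
    n_channels <- check_count(n_channels, "n_channels")
    full <- montage_1010()
    if (n_channels > nrow(full)) {
      abort("`n_channels` exceeds the packaged 64-channel montage")
    }
    montage <- full[seq_len(n_channels), ]
  } else {
    montage <- as_montage(montage)
  }
  sample_rate <- check_number(sample_rate, "sample_rate", min = 1)
  duration <- check_number(duration, "duration", min = 0)
  n_samples <- duration * sample_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    abort("`duration` times `sample_rate` must be an integer sample count")
  }
  if (inherits(oscillators, "oscillator_spec")) oscillators <- list(oscillators)
  if (inherits(couplings, "effect_spec")) couplings <- list(couplings)
  osc_names <- vapply(oscillators, function(o) {
    if (!inherits(o, "oscillator_spec")) {
      abort("`oscillators` must be a list of oscillator_spec objects")
    }
    missing_ch <- setdiff(montage$channel, names(o$topography))
    if (length(missing_ch)) {
      abort(sprintf("oscillator '%s' topography lacks channel(s): %s",
                    o$name, paste(missing_ch, collapse = ", ")))
    }
    o$name
  }, character(1))
  if (anyDuplicated(osc_names)) abort("duplicate oscillator names")
  for (cp in couplings) {
    if (!inherits(cp, "effect_spec")) {
      abort("`couplings` must be a list of effect_spec objects")
    }
    if (!cp$oscillator %in% osc_names) {
      abort(sprintf("coupling for outcome '%s' references unknown oscillator '%s'",
                    cp$outcome, cp$oscillator))
    }
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort("`age_range` must be c(lo, hi) with lo < hi")
  }
  if (prop_male < 0 || prop_male > 1) abort("`prop_male` must be in [0, 1]")
  for (nm in c("age_slope", "gender_slope")) {
    v <- get(nm)
    if (!length(v) %in% c(1L, 50L)) {
      abort(sprintf("`%s` must be a scalar or a length-50 vector", nm))
    }
  }
  measurement_sd <- check_number(measurement_sd, "measurement_sd", min = 0)
  if (length(group_labels) != length(group_probs) ||
      any(group_probs < 0) || sum(group_probs) <= 0) {
    abort("`group_labels`/`group_probs` mismatch or invalid probabilities")
  }
  structure(
    list(
      n_subjects = n_subjects, montage = montage,
      sample_rate = sample_rate, duration = duration,
      noise_exponent = noise_exponent, background_level = background_level,
      oscillators = oscillators, couplings = couplings,
      null_outcomes = null_outcomes,
      age_range = age_range, prop_male = prop_male,
      age_slope = age_slope, gender_slope = gender_slope,
      measurement_sd = measurement_sd, outcome_floor = outcome_floor,
      group_labels = group_labels,
      group_probs = group_probs / sum(group_probs),
      seed = check_count(seed, "seed", min = 0L)
    ),
    class = "cohort_spec"
  )
}

symptom_dimension_names <- function() {
  c("social_interpersonal", "anxious", "depressive", "somatic", "anomalous")
}

# subject-level draws shared by the feature-level and time-domain paths;
# must be called inside local_seed() so both paths agree given the seed
draw_subjects_and_latents <- function(spec) {
  n <- spec$n_subjects
  subjects <- tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = runif(n, spec$age_range[1], spec$age_range[2]),
    gender = rbinom(n, 1, spec$prop_male),
    diagnosis = sample(spec$group_labels, n, replace = TRUE,
                       prob = spec$group_probs)
  )
  for (sym in symptom_dimension_names()) subjects[[sym]] <- rnorm(n)

  n_osc <- length(spec$oscillators)
  latents <- matrix(0, n, n_osc)
  if (n_osc > 0) {
    colnames(latents) <- vapply(spec$oscillators, `[[`, "", "name")
    for (j in seq_len(n_osc)) {
      o <- spec$oscillators[[j]]
      latents[, j] <- rnorm(n, o$mean_log_power, o$between_subject_sd)
    }
  }

  outcomes <- draw_outcomes(spec, subjects, latents)
  if (ncol(outcomes) > 0) subjects <- dplyr::bind_cols(subjects, outcomes)
  list(subjects = subjects, latents = latents)
}

draw_outcomes <- function(spec, subjects, latents) {
  n <- spec$n_subjects
  out <- list()
  outcome_names <- unique(vapply(spec$couplings, `[[`, "", "outcome"))
  for (nm in outcome_names) {
    eff <- Filter(function(cp) cp$outcome == nm, spec$couplings)
    y <- numeric(n)
    for (cp in eff) y <- y + cp$slope * latents[, cp$oscillator]
    y <- y + rnorm(n, 0, eff[[1]]$noise_sd)
    if (nm %in% spec$outcome_floor) y <- pmax(y, 0)
    out[[nm]] <- y
  }
  for (nm in spec$null_outcomes) out[[nm]] <- rnorm(n)
  as_tibble(out)
}

# Gaussian spectral profile of an oscillator over integer bins, 1 at centre
oscillator_bump <- function(osc, freqs = 1:50) {
  sigma <- osc$bandwidth / 2
  exp(-((freqs - osc$center_frequency)^2) / (2 * sigma^2))
}

background_log_power <- function(spec, freqs = 1:50) {
  spec$background_level - spec$noise_exponent * log(freqs)
}

#' Generate a feature-level synthetic cohort
#'
#' Fast path that draws the subject x (channel x frequency) log-power table
#' directly from the latent model, skipping time-domain synthesis: each
#' feature value is background log power, plus `topography * bump * L` per
#' oscillator, plus covariate terms, plus N(0, `measurement_sd`) measurement
#' noise. Statistically consistent with [simulate_cohort()] followed by
#' [spectral_features()] at the oscillator bins (see vignette for the nature
#' of the approximation).
#'
#' @param spec A [cohort_spec()].
#' @return A list with `features` (tibble, `subject_id` + one column per
#'   feature), `subjects` (metadata + outcomes tibble) and `latents` (tibble
#'   of ground-truth per-subject band log powers, for test oracles; the
#'   pipeline never reads it).
#' @export
simulate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  local_seed(spec$seed, {
    sl <- draw_subjects_and_latents(spec)
    n <- spec$n_subjects
    channels <- spec$montage$channel
    freqs <- 1:50
    p <- length(channels) * length(freqs)

    age_c <- sl$subjects$age - mean(spec$age_range)
    age_sl <- rep(spec$age_slope, length.out = 50)
    gen_sl <- rep(spec$gender_slope, length.out = 50)

    bg <- background_log_power(spec, freqs)
    # n x 50 covariate surface, shared by all channels
    cov_term <- outer(age_c, age_sl) +
      outer(as.numeric(sl$subjects$gender), gen_sl)

    M <- matrix(0, n, p)
    col <- 0
    for (ch in channels) {
      blk <- matrix(bg, n, 50, byrow = TRUE) + cov_term
      for (j in seq_along(spec$oscillators)) {
        o <- spec$oscillators[[j]]
        w <- o$topography[[ch]]
        if (w > 0) blk <- blk + outer(sl$latents[, j], w * oscillator_bump(o))
      }
      M[, col + 1:50] <- blk
      col <- col + 50
    }
    M <- M + matrix(rnorm(n * p, 0, spec$measurement_sd), n, p)
    colnames(M) <- feature_names(spec$montage, freqs)

    list(
      features = dplyr::bind_cols(
        tibble(subject_id = sl$subjects$subject_id),
        as_tibble(as.data.frame(M))
      ),
      subjects = sl$subjects,
      latents = dplyr::bind_cols(
        tibble(subject_id = sl$subjects$subject_id),
        as_tibble(as.data.frame(sl$latents))
      )
    )
  })
}

#' Generate a time-domain synthetic cohort
#'
#' Slow path producing one multichannel recording per subject: a 1/f
#' background (independently shaped white noise per channel, one-sided PSD
#' `exp(background_level) * f^-noise_exponent` uV^2/Hz, flattened below
#' 0.5 Hz) plus, per oscillator, band-pass-filtered Gaussian noise shared
#' across channels and scaled per channel so the added band power matches the
#' subject's latent band log power under the oscillator's topography.
#'
#' @param spec A [cohort_spec()]. Keep `duration`/`n_subjects` modest: the
#'   raw signal array is `n_channels * duration * sample_rate` doubles per
#'   subject.
#' @return A list with `recordings` (class `eeg_recordings`: named list of
#'   channels x samples matrices, `sample_rate`, `montage`), `subjects`, and
#'   `latents` as in [simulate_feature_cohort()].
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_samp <- as.integer(round(spec$duration * spec$sample_rate))
  if (n_samp < 2) abort("`duration` too short for time-domain synthesis")
  local_seed(spec$seed, {
    sl <- draw_subjects_and_latents(spec)
    channels <- spec$montage$channel
    fs <- spec$sample_rate
    freqs <- 1:50
    bg <- background_log_power(spec, freqs)

    # frequency response for 1/f shaping of white noise
    k <- 0:(n_samp - 1)
    fk <- k * fs / n_samp
    fk <- pmin(fk, fs - fk)              # alias to [0, fs/2]
    f_eff <- pmax(fk, 0.5)               # flatten below 0.5 Hz
    H <- sqrt(fs * exp(spec$background_level) * f_eff^(-spec$noise_exponent) / 2)
    H[1] <- 0

    age_c <- sl$subjects$age - mean(spec$age_range)
    age_sl <- rep(spec$age_slope, length.out = 50)
    gen_sl <- rep(spec$gender_slope, length.out = 50)

    recs <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      m <- matrix(0, length(channels), n_samp)
      for (c_idx in seq_along(channels)) {
        wht <- rnorm(n_samp)
        x <- Re(stats::fft(stats::fft(wht) * H, inverse = TRUE)) / n_samp
        # covariate effect: uniform gain over the analysis band (mean slope)
        gain <- exp(mean(age_sl) * age_c[i] +
                      mean(gen_sl) * sl$subjects$gender[i])
        m[c_idx, ] <- x * sqrt(gain)
      }
      for (j in seq_along(spec$oscillators)) {
        o <- spec$oscillators[[j]]
        band <- c(max(o$center_frequency - o$bandwidth / 2, 0.5),
                  min(o$center_frequency + o$bandwidth / 2, fs / 2 * 0.99))
        bf <- signal::butter(4, band / (fs / 2), type = "pass")
        s0 <- signal::filtfilt(bf, rnorm(n_samp))
        s0 <- s0 / sd(s0)
        bump <- oscillator_bump(o, freqs)
        for (c_idx in seq_along(channels)) {
          w <- o$topography[[channels[c_idx]]]
          if (w <= 0) next
          v_target <- sum(pmax(
            exp(bg + w * bump * sl$latents[i, j]) - exp(bg), 0
          ))
          if (v_target > 0) m[c_idx, ] <- m[c_idx, ] + s0 * sqrt(v_target)
        }
      }
      rownames(m) <- channels
      recs[[i]] <- m
    }
    names(recs) <- sl$subjects$subject_id

    list(
      recordings = structure(
        list(signals = recs, sample_rate = fs, montage = spec$montage),
        class = "eeg_recordings"
      ),
      subjects = sl$subjects,
      latents = dplyr::bind_cols(
        tibble(subject_id = sl$subjects$subject_id),
        as_tibble(as.data.frame(sl$latents))
      )
    )
  })
}

#' @export
print.eeg_recordings <- function(x, ...) {
  n <- length(x$signals)
  dims <- dim(x$signals[[1]])
  cat(sprintf(
    "<eeg_recordings>  %d subject(s), %d channels x %d samples @ %g Hz\n",
    n, dims[1], dims[2], x$sample_rate
  ))
  invisible(x)
}

#' Preset synthetic cohorts
#'
#' Bundled study conditions used by the package's own validation suites:
#' \describe{
#'   \item{"acceptance"}{n = 200 subjects, full 64-channel montage, one
#'     6 Hz theta-band oscillator peaking at F4 with a planted negative
#'     coupling (slope -1, noise SD 1.5, between-subject SD 1) to the outcome
#'     `score` -- the planted-signal recovery condition.}
#'   \item{"desk"}{n = 60 subjects, 4 channels (200 features), no planted
#'     coupling, one pure-noise outcome `score` -- the null-calibration
#'     condition.}
#'   \item{"null64"}{n = 60 subjects, full montage, no oscillators, one
#'     pure-noise outcome -- a 1/f-only null cohort.}
#' }
#'
#' @param name Preset name.
#' @param n_subjects,seed Optional overrides.
#' @return A [cohort_spec()].
#' @export
cohort_preset <- function(name = c("acceptance", "desk", "null64"),
                          n_subjects = NULL, seed = 1) {
  name <- match.arg(name)
  switch(name,
    acceptance = {
      m <- montage_1010()
      osc <- oscillator_spec(
        name = "theta6", center_frequency = 6, bandwidth = 2,
        mean_log_power = 2, between_subject_sd = 1,
        topography = topo_gaussian(m, "F4", width = 0.6)
      )
      cohort_spec(
        n_subjects = n_subjects %||% 200, montage = m,
        duration = 60,
        oscillators = list(osc),
        couplings = list(effect_spec("score", "theta6", slope = -1,
                                     noise_sd = 1.5)),
        seed = seed
      )
    },
    desk = cohort_spec(
      n_subjects = n_subjects %||% 60, n_channels = 4,
      duration = 60, null_outcomes = "score", seed = seed
    ),
    null64 = cohort_spec(
      n_subjects = n_subjects %||% 60, n_channels = 64,
      duration = 60, null_outcomes = "score", seed = seed
    )
  )
}
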