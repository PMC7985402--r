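#' Welch-averaged log power spectrum in 1-Hz bins
#'
#' Reduces one multichannel recording to log band power per channel and
#' 1-Hz frequency bin. The recording is cut into Hann-windowed segments of
#' `window_length` samples (50% overlap by default), a periodogram is computed
#' per segment and channel, periodograms are averaged across segments, spectral
#' lines are summed into 1-Hz bins centred on the integers `freqs` (bin b
#' covers the half-open interval \[b - 0.5, b + 0.5) Hz), and the result is
#' natural-log transformed.
#'
#' At 512 Hz sampling with the default 512-sample window the native resolution
#' is exactly 1 Hz, so each bin holds a single FFT line.
#'
#' @param recording Numeric matrix, channels x samples (rownames are channel
#'   names; unnamed channels are numbered).
#' @param sample_rate Sampling rate in Hz.
#' @param window_length Segment/window length in samples (default 512).
#' @param overlap Fractional overlap between consecutive segments in \[0, 1).
#' @param freqs Integer bin centres in Hz (default 1--50).
#' @param log_floor Power floor applied before the log so degenerate (all-zero)
#'   synthetic channels do not produce -Inf.
#' @return A tibble with columns `channel`, `freq`, `log_power` (log uV^2 per
#'   bin), ordered by channel then frequency.
#' @export
compute_power_spectrum <- function(recording, sample_rate,
                                   window_length = 512, overlap = 0.5,
                                   freqs = 1:50, log_floor = 1e-20) {
  if (!is.matrix(recording) || !is.numeric(recording)) {
    abort("`recording` must be a numeric channels x samples matrix")
  }
  if (any(!is.finite(recording))) {
    abort("`recording` contains non-finite samples")
  }
  sample_rate <- check_number(sample_rate, "sample_rate", min = 1)
  window_length <- check_count(window_length, "window_length", min = 2L)
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  n_samp <- ncol(recording)
  if (n_samp < window_length) {
    abort("recording is shorter than one analysis window")
  }
  if (sample_rate / window_length > 1 + 1e-9) {
    abort("`window_length` too short for 1 Hz resolution at this sample rate")
  }
  channels <- rownames(recording) %||% as.character(seq_len(nrow(recording)))

  w <- as.numeric(signal::hanning(window_length))
  hop <- max(1L, as.integer(round(window_length * (1 - overlap))))
  starts <- seq.int(1L, n_samp - window_length + 1L, by = hop)

  line_freq <- (0:(window_length %/% 2)) * sample_rate / window_length
  bin_of <- floor(line_freq + 0.5)  # [b - 0.5, b + 0.5) half-open

  acc <- matrix(0, nrow(recording), length(freqs))
  for (s in starts) {
    seg <- recording[, s:(s + window_length - 1L), drop = FALSE]
    pg <- segment_periodogram(seg, w)
    for (j in seq_along(freqs)) {
      sel <- bin_of == freqs[j]
      acc[, j] <- acc[, j] + rowSums(pg[, sel, drop = FALSE])
    }
  }
  pw <- acc / length(starts)
  tibble(
    channel = rep(channels, each = length(freqs)),
    freq = rep(as.numeric(freqs), times = length(channels)),
    log_power = as.vector(t(log(pmax(pw, log_floor))))
  )
}

# One-sided periodogram of each row of `seg` after applying window `w`,
# scaled so that the bin powers sum to the window-gain-corrected mean square:
#   sum_k P_k = sum_t (x_t w_t)^2 / sum_t w_t^2       (Parseval)
# Returns channels x (floor(N/2) + 1) matrix; columns are FFT lines at
# frequencies (0:(N/2)) * fs / N.
segment_periodogram <- function(seg, w) {
  n <- length(w)
  half <- n %/% 2
  xw <- sweep(seg, 2, w, `*`)
  X <- t(stats::mvfft(t(xw)))
  p <- Mod(X[, 1:(half + 1), drop = FALSE])^2 / (n * sum(w^2))
  mult <- c(1, rep(2, half - 1), if (n %% 2 == 0) 1 else 2)
  sweep(p, 2, mult, `*`)
}

#' Build the subject x (channel x frequency) feature table
#'
#' Applies [compute_power_spectrum()] to every recording of a recording set
#' and assembles the wide feature table used by the forest models: one row
#' per subject, one column per `"<channel>_<freq>Hz"` feature.
#'
#' @param recordings An `eeg_recordings` object (see [simulate_cohort()]) or a
#'   named list of channels x samples matrices plus `sample_rate`.
#' @param sample_rate Sampling rate in Hz; taken from the recording set when
#'   available.
#' @inheritParams compute_power_spectrum
#' @return A tibble: `subject_id` plus `n_channels * length(freqs)` numeric
#'   feature columns.
#' @export
spectral_features <- function(recordings, sample_rate = NULL,
                              window_length = 512, overlap = 0.5,
                              freqs = 1:50) {
  if (inherits(recordings, "eeg_recordings")) {
    sample_rate <- sample_rate %||% recordings$sample_rate
    sigs <- recordings$signals
  } else if (is.list(recordings)) {
    sigs <- recordings
  } else {
    abort("`recordings` must be an eeg_recordings object or list of matrices")
  }
  if (is.null(sample_rate)) abort("`sample_rate` is required")
  ids <- names(sigs) %||% sprintf("S%03d", seq_along(sigs))

  rows <- purrr::map(sigs, function(m) {
    sp <- compute_power_spectrum(m, sample_rate, window_length, overlap, freqs)
    setNames(sp$log_power, sprintf("%s_%dHz", sp$channel, as.integer(sp$freq)))
  })
  feat <- do.call(rbind, rows)
  out <- as_tibble(as.data.frame(feat))
  dplyr::bind_cols(tibble(subject_id = ids), out)
}
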