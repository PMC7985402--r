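#' Standard 64-channel 10/10 scalp montage
#'
#' Returns the electrode montage used throughout the package: 64 channels of
#' the extended 10/20 ("10/10") naming scheme, with schematic 2-D top-view
#' coordinates (nose up, left ear at negative x). The coordinate system is a
#' unit-head projection intended for topographic maps and distance-based
#' synthetic topographies, not a digitisation of physical electrode positions.
#'
#' @return A tibble with columns `channel`, `x`, `y`.
#' @examples
#' m <- montage_1010()
#' nrow(m) # 64
#' @export
montage_1010 <- function() {
  rows <- list(
    list(y = 1.00, ch = c("Fp1", "Fpz", "Fp2")),
    list(y = 0.78, ch = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y = 0.55, ch = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    list(y = 0.28, ch = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
                          "FC6", "FT8")),
    list(y = 0.00, ch = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                          "T8")),
    list(y = -0.28, ch = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                           "CP6", "TP8")),
    list(y = -0.55, ch = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6",
                           "P8")),
    list(y = -0.78, ch = c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8")),
    list(y = -1.00, ch = c("O1", "Oz", "O2")),
    list(y = -1.15, ch = "Iz")
  )
  out <- purrr::map_dfr(rows, function(r) {
    k <- length(r$ch)
    half <- sqrt(max(1.12 - r$y^2, 0.05))
    x <- if (k == 1) 0 else seq(-half, half, length.out = k)
    tibble(channel = r$ch, x = x, y = r$y)
  })
  out
}

# Validate a montage-like data frame and return it as a tibble.
as_montage <- function(montage) {
  if (!is.data.frame(montage) ||
      !all(c("channel", "x", "y") %in% names(montage))) {
    abort("`montage` must be a data frame with columns channel, x, y")
  }
  if (anyDuplicated(montage$channel)) {
    abort("`montage` has duplicated channel names")
  }
  as_tibble(montage[c("channel", "x", "y")])
}

#' Feature naming for channel-by-frequency predictors
#'
#' Features are named `"<channel>_<freq>Hz"` (e.g. `"Fz_10Hz"`).
#' `feature_names()` builds the full grid for a montage; `parse_features()`
#' splits names back into channel and frequency.
#'
#' @param montage A montage tibble (see [montage_1010()]).
#' @param freqs Integer frequency-bin centres in Hz.
#' @return `feature_names()`: character vector of length
#'   `nrow(montage) * length(freqs)`, frequency varying fastest within channel.
#' @export
feature_names <- function(montage = montage_1010(), freqs = 1:50) {
  montage <- as_montage(montage)
  as.vector(vapply(montage$channel,
                   function(ch) sprintf("%s_%dHz", ch, as.integer(freqs)),
                   character(length(freqs))))
}

#' @rdname feature_names
#' @param x Character vector of feature names.
#' @return `parse_features()`: tibble with columns `feature`, `channel`,
#'   `freq` (NA where a name does not match the convention).
#' @export
parse_features <- function(x) {
  m <- regmatches(x, regexec("^(.+)_([0-9]+)Hz$", x))
  ch <- vapply(m, function(g) if (length(g) == 3) g[[2]] else NA_character_,
               character(1))
  fr <- vapply(m, function(g) if (length(g) == 3) as.numeric(g[[3]]) else
    NA_real_, numeric(1))
  tibble(feature = x, channel = ch, freq = fr)
}

# Extract the numeric feature matrix from a feature table (drops subject_id
# and any other non-numeric column), keeping rownames = subject ids.
feature_matrix <- function(features) {
  if (is.matrix(features)) {
    storage.mode(features) <- "double"
    return(features)
  }
  if (!is.data.frame(features)) {
    abort("`features` must be a data frame or numeric matrix")
  }
  ids <- if ("subject_id" %in% names(features)) {
    as.character(features$subject_id)
  } else {
    as.character(seq_len(nrow(features)))
  }
  keep <- vapply(features, is.numeric, logical(1))
  keep[names(features) == "subject_id"] <- FALSE
  m <- as.matrix(features[keep])
  rownames(m) <- ids
  m
}
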