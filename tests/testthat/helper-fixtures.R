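# Shared fixture builders: everything is generated in code at test time.

# tiny montage for cheap cohorts
tiny_montage <- function(k = 4) montage_1010()[seq_len(k), ]

# a named flat topography over a montage
flat_topo <- function(montage, w = 1) {
  stats::setNames(rep(w, nrow(montage)), montage$channel)
}

# random feature matrix with spectral naming, n x (channels x 50)
random_features <- function(n, montage = tiny_montage(), seed = 1) {
  withr::with_seed(seed, {
    p <- nrow(montage) * 50
    m <- matrix(stats::rnorm(n * p), n)
    colnames(m) <- feature_names(montage)
    m
  })
}

# cohort with one planted predictive feature block, used by forest tests
planted_data <- function(n = 60, p = 50, slope = 2, noise = 0.3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n)
    colnames(X) <- paste0("f", seq_len(p))
    y <- slope * (X[, min(10, p)] > 0) + stats::rnorm(n, 0, noise)
    list(X = X, y = y)
  })
}
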