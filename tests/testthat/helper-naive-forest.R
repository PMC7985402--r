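# Naive explicit-loop reimplementation of the bagged-tree ensemble, used as
# an independent oracle for the compiled implementation. It follows the
# documented algorithm literally (Lehmer RNG, bootstrap multiplicities,
# variance-reduction split search over (value, row)-ordered instances,
# midpoint thresholds, OOB averaging) with plain R loops and double
# arithmetic, and must reproduce the compiled OOB predictions exactly.

naive_rng <- function(seed) {
  m <- 2147483647
  s <- seed - trunc(seed / (m - 1)) * (m - 1)
  if (s < 0) s <- s + (m - 1)
  env <- new.env()
  env$s <- s + 1
  env$unif <- function() {
    prod <- 48271 * env$s
    q <- trunc(prod / m)
    env$s <- prod - q * m
    env$s / m
  }
  env$below <- function(k) floor(env$unif() * k)  # in 0..k-1
  env
}

naive_forest_oob <- function(X, y, n_trees, mtry, min_leaf, seed) {
  n <- nrow(X)
  p <- ncol(X)
  rng <- naive_rng(seed)

  grow <- function(rows, row_count, perm) {
    node <- list(feature = NA, threshold = NA, left = NULL, right = NULL)
    nn <- 0
    sy <- 0
    for (r in rows) {
      for (c in seq_len(row_count[r])) sy <- sy + y[r]
      nn <- nn + row_count[r]
    }
    node$value <- sy / nn
    if (nn < 2 * min_leaf) return(node)

    swaps <- integer(mtry)
    for (j in seq_len(mtry)) {
      rpos <- j + rng$below(p - j + 1)
      tmp <- perm[j]; perm[j] <- perm[rpos]; perm[rpos] <- tmp
      swaps[j] <- rpos
    }

    best_gain <- 0
    best_f <- NA
    best_thr <- NA
    for (j in seq_len(mtry)) {
      f <- perm[j]
      xcol <- X[, f]
      sorted_rows <- rows[order(xcol[rows])]  # rows ascending => stable ties
      k <- 0
      sl <- 0
      prev_x <- 0
      have <- FALSE
      for (r in sorted_rows) {
        x <- xcol[r]
        if (have && k >= min_leaf && nn - k >= min_leaf && prev_x < x) {
          sr <- sy - sl
          gain <- sl * sl / k + sr * sr / (nn - k) - sy * sy / nn
          if (gain > best_gain) {
            best_gain <- gain
            best_f <- f
            mid <- (prev_x + x) / 2
            if (!(mid < x)) mid <- prev_x
            best_thr <- mid
          }
        }
        for (c in seq_len(row_count[r])) {
          sl <- sl + y[r]
          k <- k + 1
        }
        prev_x <- x
        have <- TRUE
      }
    }
    # note: swap undo restores perm, but perm is local to this call chain;
    # the compiled code shares one pool, so mirror by undoing before recursing
    for (j in rev(seq_len(mtry))) {
      tmp <- perm[j]; perm[j] <- perm[swaps[j]]; perm[swaps[j]] <- tmp
    }

    if (is.na(best_f)) return(node)
    xcol <- X[, best_f]
    lrows <- rows[xcol[rows] <= best_thr]
    rrows <- rows[xcol[rows] > best_thr]
    node$feature <- best_f
    node$threshold <- best_thr
    node$left <- grow(lrows, row_count, perm)
    node$right <- grow(rrows, row_count, perm)
    node
  }

  predict_node <- function(node, xrow) {
    while (!is.na(node$feature)) {
      node <- if (xrow[node$feature] <= node$threshold) node$left else
        node$right
    }
    node$value
  }

  oob_sum <- numeric(n)
  oob_cnt <- integer(n)
  for (b in seq_len(n_trees)) {
    row_count <- integer(n)
    for (i in seq_len(n)) {
      d <- rng$below(n) + 1
      row_count[d] <- row_count[d] + 1
    }
    rows <- which(row_count > 0)
    tree <- grow(rows, row_count, seq_len(p))
    for (r in which(row_count == 0)) {
      oob_sum[r] <- oob_sum[r] + predict_node(tree, X[r, ])
      oob_cnt[r] <- oob_cnt[r] + 1
    }
  }
  list(oob_sum = oob_sum, oob_count = oob_cnt,
       oob_pred = oob_sum / oob_cnt)
}
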