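# Independent brute-force oracles: straightforward per-pixel double loops
# written directly from the feature definitions, sharing no code with the
# package's vectorized implementations.

# symmetric border reflection of a scalar index onto 1..n
oracle_reflect <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracle_window_values <- function(mat, x, y, win_h, win_w) {
  rh <- (win_h - 1L) %/% 2L
  rw <- (win_w - 1L) %/% 2L
  vals <- numeric(0)
  for (dx in -rw:rw) {
    for (dy in -rh:rh) {
      vals <- c(vals,
                mat[oracle_reflect(x + dy, nrow(mat)),
                    oracle_reflect(y + dx, ncol(mat))])
    }
  }
  vals
}

# feature: one of "local_contrast", "global_contrast", "histogram_spread",
# "fuzzy_entropy", "fuzzy_std"
oracle_feature_map <- function(image, win_h, win_w, feature,
                               mu = NULL, a_coeff = 1) {
  out <- matrix(NA_real_, nrow(image), ncol(image))
  nm <- win_h * win_w
  for (x in seq_len(nrow(image))) {
    for (y in seq_len(ncol(image))) {
      f <- oracle_window_values(image, x, y, win_h, win_w)
      out[x, y] <- switch(feature,
        local_contrast = (max(f) - min(f)) / 255,
        histogram_spread = {
          hmax <- max(table(f))
          (max(f) - min(f)) / hmax
        },
        fuzzy_entropy = {
          tot <- 0
          for (fi in f) {
            p <- sum(f == fi) / nm
            term <- 0
            if (p > 0) term <- term + p * log(p)
            if (p < 1) term <- term + (1 - p) * log(1 - p)
            tot <- tot + term
          }
          -a_coeff * tot / log(nm)
        },
        global_contrast = {
          m <- oracle_window_values(mu, x, y, win_h, win_w)
          if (sum(m) == 0) 0 else {
            mloc <- mean(f)
            min(1, 2 * sqrt(sum((f - mloc)^2 * m) / sum(m)) / 255)
          }
        },
        fuzzy_std = {
          m <- oracle_window_values(mu, x, y, win_h, win_w)
          if (sum(m) == 0) 0 else {
            mloc <- mean(f)
            sqrt(sum((f - mloc)^2 * m) / sum(m) / nm)
          }
        },
        stop("unknown feature"))
    }
  }
  out
}

# AUC by exhaustive positive-negative pair comparison, ties credited 0.5
oracle_auc <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      if (p > q) wins <- wins + 1
      else if (p == q) wins <- wins + 0.5
    }
  }
  wins / (length(pos_scores) * length(neg_scores))
}

rand_gray <- function(h, w, seed, levels = 256L) {
  set.seed(seed)
  matrix(sample.int(levels, h * w, replace = TRUE) - 1L, h, w)
}
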