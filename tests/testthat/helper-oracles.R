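# Independent counting/looping oracles for the histogram and window
# metrics. These deliberately avoid the package's vectorized code paths:
# explicit loops, explicit accumulators.

oracle_bin <- function(x, lo, hi, bins) {
  if (hi <= lo) return(rep(1L, length(x)))
  out <- integer(length(x))
  w <- (hi - lo) / bins
  for (i in seq_along(x)) {
    b <- floor((x[i] - lo) / w) + 1
    if (b > bins) b <- bins
    out[i] <- b
  }
  out
}

oracle_entropy <- function(img, bins = 256L, rng = range(img)) {
  idx <- oracle_bin(as.vector(img), rng[1], rng[2], bins)
  counts <- rep(0L, bins)
  for (b in idx) counts[b] <- counts[b] + 1L
  h <- 0
  n <- length(idx)
  for (c in counts) if (c > 0) {
    p <- c / n
    h <- h - p * log2(p)
  }
  h
}

oracle_joint_entropy <- function(a, b, bins = 256L) {
  ia <- oracle_bin(as.vector(a), min(a), max(a), bins)
  ib <- oracle_bin(as.vector(b), min(b), max(b), bins)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(ia))
    counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1L
  n <- length(ia)
  h <- 0
  for (c in counts) if (c > 0) {
    p <- c / n
    h <- h - p * log2(p)
  }
  h
}

oracle_nmi <- function(a, b, bins = 256L) {
  h1 <- oracle_entropy(a, bins)
  h2 <- oracle_entropy(b, bins)
  h12 <- oracle_joint_entropy(a, b, bins)
  2 * (h1 + h2 - h12) / (h1 + h2)
}

# Textbook per-window mean SSIM: uniform win x win window, sample (n-1)
# variance/covariance, valid windows only.
oracle_ssim <- function(a, b, win = 7L, K1 = 0.01, K2 = 0.03,
                        data_range = max(a, b) - min(a, b)) {
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  n <- win * win
  vals <- c()
  for (i in seq_len(nrow(a) - win + 1L)) {
    for (j in seq_len(ncol(a) - win + 1L)) {
      wa <- a[i:(i + win - 1L), j:(j + win - 1L)]
      wb <- b[i:(i + win - 1L), j:(j + win - 1L)]
      ua <- mean(wa); ub <- mean(wb)
      va <- sum((wa - ua)^2) / (n - 1)
      vb <- sum((wb - ub)^2) / (n - 1)
      cab <- sum((wa - ua) * (wb - ub)) / (n - 1)
      vals <- c(vals, ((2 * ua * ub + C1) * (2 * cab + C2)) /
                      ((ua^2 + ub^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

rand_img <- function(seed, nr = 64, nc = nr, levels = 256) {
  set.seed(seed)
  matrix(sample.int(levels, nr * nc, replace = TRUE) - 1, nr, nc)
}

# a small two-channel phantom pair, mixed if alpha given
phantom_pair <- function(seed, rho = 0, a12 = 0, a21 = 0, ...) {
  sp <- phantom_spec(coloc_fraction = rho,
                     true_alpha = matrix(c(0, a21, a12, 0), 2, 2),
                     seed = seed, ...)
  st <- generate_ground_truth(sp)
  if (a12 != 0 || a21 != 0) st <- apply_mixing(st, sp$true_alpha)
  st
}
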