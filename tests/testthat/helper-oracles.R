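# Independent reference implementations used as oracles. Deliberately naive
# (loops, direct sums) and kept apart from the package's code paths.

# ReliefF by the book: explicit loops, Euclidean neighbours, ties broken by
# lower index, range-normalised diffs averaged over m*k.
naive_relieff <- function(x, y, k, m = nrow(x)) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  rng <- numeric(d)
  for (f in seq_len(d)) rng[f] <- max(x[, f]) - min(x[, f])
  w <- numeric(d)
  targets <- rep_len(seq_len(n), m)
  for (i in targets) {
    dist <- numeric(n)
    for (j in seq_len(n)) dist[j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    dist[i] <- Inf
    same <- which(y == y[i] & seq_len(n) != i)
    diff <- which(y != y[i])
    hits <- same[order(dist[same], same)][seq_len(k)]
    misses <- diff[order(dist[diff], diff)][seq_len(k)]
    for (f in seq_len(d)) {
      if (rng[f] == 0) next
      hd <- sum(abs(x[hits, f] - x[i, f])) / rng[f]
      md <- sum(abs(x[misses, f] - x[i, f])) / rng[f]
      w[f] <- w[f] + (md - hd) / (m * k)
    }
  }
  w
}

# AUC as the Mann-Whitney pairwise statistic by exhaustive enumeration.
pair_count_auc <- function(prob, y) {
  pos <- prob[y == 1]
  neg <- prob[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Otsu by brute force: evaluate the between-class variance of {<=t}, {>t}
# for every candidate t and return the smallest maximizer.
brute_otsu <- function(counts) {
  levels <- 0:255
  n <- sum(counts)
  best_t <- 0
  best_v <- -1
  for (t in levels) {
    in0 <- levels <= t
    w0 <- sum(counts[in0]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) {
      v <- 0
    } else {
      mu0 <- sum(levels[in0] * counts[in0]) / sum(counts[in0])
      mu1 <- sum(levels[!in0] * counts[!in0]) / sum(counts[!in0])
      v <- w0 * w1 * (mu0 - mu1)^2
    }
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Row autocorrelation at a given lag by direct summation over pixel pairs.
direct_row_autocorr <- function(gray, lag) {
  a <- gray[seq_len(nrow(gray) - lag), , drop = FALSE]
  b <- gray[(lag + 1):nrow(gray), , drop = FALSE]
  va <- as.vector(a)
  vb <- as.vector(b)
  sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
}
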