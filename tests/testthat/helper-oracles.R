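# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: ranking by sorting + the Pearson
# formula, hand-rolled Kruskal-Wallis H, Floyd-Warshall distances, direct
# triangle counting, and pair-enumeration AUC.

oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

# midrank by sorting (no rank())
oracle_midrank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_spearman <- function(a, b)
  oracle_pearson(oracle_midrank(a), oracle_midrank(b))

# tie-corrected Kruskal-Wallis H and chi-square p
oracle_kruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- oracle_midrank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / C
  list(H = H, p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    tri <- sum(vapply(seq_len(ncol(pairs)), function(c)
      adj[pairs[1, c], pairs[2, c]] > 0, logical(1)))
    tri / ncol(pairs)
  }, numeric(1))
}

# AUC by exhaustive concordant-pair counting
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# narrow brick-wall band-pass + Hilbert magnitude (independent of the
# Morlet path)
oracle_band_envelope <- function(x, rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * rate
  keep <- f >= lo & f <= hi            # positive-frequency band only
  X[!keep] <- 0
  Mod(stats::fft(2 * X, inverse = TRUE) / n)
}

random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a + t(a)
}
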