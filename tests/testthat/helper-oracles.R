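# Independent oracles for the test suite. Each deliberately uses a
# different algorithm than the production path it checks.

ALPH_DNA <- c("A", "C", "G", "T")
ALPH_PROT <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_string <- function(n, letters0) {
  paste(sample(letters0, n, replace = TRUE), collapse = "")
}

# Naive all-pairs window distances: explicit per-window character
# comparison, O(l n^2), independent of the diagonal cumulative-sum DP.
naive_window_dists <- function(s1, s2, l) {
  x <- strsplit(s1, "")[[1]]
  y <- strsplit(s2, "")[[1]]
  m <- length(x) - l + 1L
  W1 <- vapply(seq_len(m), function(u) x[u:(u + l - 1L)], character(l))
  W2 <- vapply(seq_len(m), function(v) y[v:(v + l - 1L)], character(l))
  D <- matrix(0L, m, m)
  for (u in seq_len(m)) D[u, ] <- as.integer(colSums(W1[, u] != W2))
  D
}

# Naive pair aggregation: term-by-term double loop over window pairs.
naive_pair_counts <- function(s1, s2, table) {
  l <- table$params$l
  D <- naive_window_dists(s1, s2, l)
  raw <- 0; wt <- 0
  for (u in seq_len(nrow(D))) for (v in seq_len(ncol(D))) {
    cnt <- table$counts_full[D[u, v] + 1L]
    raw <- raw + cnt
    wt <- wt + cnt / (D[u, v] + 1)
  }
  list(raw = raw, weighted = wt)
}

# Straightforward reference MCL (no pruning tricks, plain loops) used to
# cross-check cluster recovery on planted instances.
naive_mcl_limit <- function(S, inflation = 1.8, iters = 60) {
  t <- nrow(S)
  A <- S
  diag(A) <- 0
  for (i in seq_len(t)) diag(A)[i] <- max(A[i, ], 1e-12)
  M <- apply(A, 2, function(col) col / sum(col))
  for (it in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- apply(M, 2, function(col) if (sum(col) > 0) col / sum(col) else col)
  }
  M
}

naive_mcl_partition <- function(S, ...) {
  M <- naive_mcl_limit(S, ...)
  att <- which(diag(M) > 1e-6)
  assign <- vapply(seq_len(nrow(M)), function(v) att[which.max(M[att, v])],
                   integer(1))
  unname(split(seq_len(nrow(M)), assign))
}

# Literal re-implementation of the greedy refinement recurrences.
naive_refine_b <- function(cluster, k, S) {
  best <- c(NA, NA); bestv <- -Inf
  for (a in cluster) for (b in cluster) {
    if (a < b && S[a, b] > bestv) { bestv <- S[a, b]; best <- c(a, b) }
  }
  dp <- best
  while (length(dp) < k) {
    pool <- setdiff(cluster, dp)
    vals <- sapply(pool, function(i) sum(S[i, dp]))
    dp <- c(dp, pool[which.max(vals)])
  }
  sort(dp)
}

naive_refine_c <- function(cluster, k, S) {
  dp <- cluster
  while (length(dp) < k) {
    pool <- setdiff(seq_len(nrow(S)), dp)
    vals <- sapply(pool, function(i) sum(S[i, dp]))
    dp <- c(dp, pool[which.max(vals)])
  }
  sort(dp)
}

# Second, independent exhaustive enumeration of the best k-subset
# (recursive, not combn-based).
naive_best_subset <- function(mat, k) {
  t <- mat$t
  best <- NULL; bestv <- Inf
  rec <- function(start, chosen) {
    if (length(chosen) == k) {
      v <- 0
      for (a in seq_along(chosen)) for (b in seq_along(chosen)) {
        if (a < b) v <- v + mat$raw[chosen[a], chosen[b]]
      }
      if (v < bestv) { bestv <<- v; best <<- chosen }
      return(invisible())
    }
    if (start > t) return(invisible())
    for (i in start:t) rec(i + 1L, c(chosen, i))
  }
  rec(1L, integer(0))
  list(indices = best, total = bestv)
}

# sample() that never unpacks a scalar into 1:x
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

# Random symmetric positive similarity matrix.
rand_sim_matrix <- function(t, lo = 1, hi = 10) {
  S <- matrix(0, t, t)
  S[upper.tri(S)] <- runif(t * (t - 1) / 2, lo, hi)
  S <- S + t(S)
  S
}

make_seq_set <- function(t, n, letters0 = ALPH_DNA) {
  sequence_set(vapply(seq_len(t), function(i) rand_string(n, letters0),
                      character(1)),
               alphabet = if (identical(letters0, ALPH_DNA)) "dna" else "protein")
}
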