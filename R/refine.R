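# Cluster refinement: turn an MCL cluster into an exactly-k reference set.
# Three cases by cluster size |C| versus k:
#   (a) |C| = k  -> take the cluster as-is;
#   (b) |C| > k  -> greedy shrink-from-pair inside the cluster: start from
#       the most similar pair, repeatedly add the cluster node with the
#       largest summed similarity to the current set;
#   (c) 1 < |C| < k -> start from the whole cluster and grow with the same
#       greedy rule over the remaining nodes of the whole graph.
# Singleton clusters are invalid. All ties break to the lowest index.

new_reference_set <- function(indices, matrix, case, cluster = NULL) {
  indices <- sort(as.integer(indices))
  structure(list(indices = indices,
                 score = score_set(indices, matrix),
                 total_count = if (inherits(matrix, "similarity_matrix"))
                   total_candidate_count(indices, matrix) else NA_real_,
                 provenance = list(case = case, cluster = cluster)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: k = %d [%s], score %.6g, total count %.6g\n",
              length(x$indices), x$provenance$case, x$score, x$total_count))
  cat("  indices:", paste(x$indices, collapse = " "), "\n")
  invisible(x)
}

#' Similarity score of an index set
#'
#' Sum of pairwise similarities over all unordered pairs inside the set
#' (each pair counted once; a global factor of two cannot change any
#' argmax). Higher means the members generate fewer candidate motifs
#' together.
#'
#' @param indices At least two distinct 1-based indices.
#' @param matrix A [similarity_matrix()] or plain symmetric matrix.
#' @return The score (double).
#' @export
score_set <- function(indices, matrix) {
  S <- if (inherits(matrix, "similarity_matrix")) matrix$sim else as.matrix(matrix)
  indices <- as.integer(indices)
  if (length(indices) < 2L) stop("need at least 2 indices", call. = FALSE)
  if (anyDuplicated(indices)) stop("indices must be distinct", call. = FALSE)
  pr <- utils::combn(sort(indices), 2L)
  sum(S[cbind(pr[1, ], pr[2, ])])
}

greedy_extend <- function(current, pool, k, S) {
  while (length(current) < k) {
    gains <- vapply(pool, function(i) sum(S[i, current]), numeric(1))
    best <- pool[which(gains == max(gains))[1]]  # ties -> lowest index
    current <- c(current, best)
    pool <- setdiff(pool, best)
  }
  current
}

#' Refine one cluster into a k-set of reference sequences
#'
#' @param cluster Sorted 1-based indices of one cluster.
#' @param k Target reference count, `1 < k < t`.
#' @param matrix A [similarity_matrix()] (or plain symmetric matrix; then
#'   raw totals are unavailable and `total_count` is `NA`).
#' @return A `reference_set`, or `NULL` for an invalid (singleton)
#'   cluster.
#' @export
refine_cluster <- function(cluster, k, matrix) {
  S <- if (inherits(matrix, "similarity_matrix")) matrix$sim else as.matrix(matrix)
  t <- nrow(S)
  cluster <- sort(as.integer(cluster))
  k <- as.integer(k)
  if (length(cluster) < 1L) stop("empty cluster", call. = FALSE)
  if (k <= 1L || k >= t) stop("'k' must satisfy 1 < k < t", call. = FALSE)
  if (length(cluster) == 1L) return(NULL)
  if (length(cluster) == k)
    return(new_reference_set(cluster, matrix, "a", cluster))
  if (length(cluster) > k) {
    # initial pair: argmax similarity inside the cluster, lexicographic ties
    sub <- S[cluster, cluster, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- -Inf
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    init <- cluster[c(best[1], best[2])]
    sel <- greedy_extend(init, setdiff(cluster, init), k, S)
    return(new_reference_set(sel, matrix, "b", cluster))
  }
  # case (c): grow the cluster from the whole graph
  sel <- greedy_extend(cluster, setdiff(seq_len(t), cluster), k, S)
  new_reference_set(sel, matrix, "c", cluster)
}

#' Select k reference sequences via clustering and refinement
#'
#' Clusters the similarity graph with MCL, refines every valid cluster to
#' an exactly-k set, scores each set by its summed internal similarity and
#' returns the best (ties: lexicographically smallest index list). If no
#' valid cluster exists, the whole node set is refined with the
#' shrink-from-pair greedy as a fallback. `k = t` is returned as the
#' identity ordering with a warning.
#'
#' @param matrix A [similarity_matrix()].
#' @param k Number of reference sequences, `1 < k < t` (or `t`).
#' @param config An [mcl_config()].
#' @return A `reference_set`; its `provenance` records the originating
#'   cluster and refinement case (`a`/`b`/`c`/`fallback`), and
#'   `clusters` attribute carries the full `cluster_set`.
#' @export
select_references <- function(matrix, k, config = mcl_config()) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  t <- matrix$t
  k <- as.integer(k)
  if (k == t) {
    warning("k = t: returning the full set in input order", call. = FALSE)
    out <- new_reference_set(seq_len(t), matrix, "identity")
    attr(out, "clusters") <- NULL
    return(out)
  }
  if (k <= 1L || k > t) stop("'k' must satisfy 1 < k < t", call. = FALSE)
  cs <- mcl_cluster(matrix, config)
  cands <- list()
  for (i in seq_along(cs$clusters)) {
    if (!cs$validity[i]) next
    rs <- refine_cluster(cs$clusters[[i]], k, matrix)
    if (!is.null(rs)) cands[[length(cands) + 1L]] <- rs
  }
  if (length(cands) == 0L) {
    rs <- refine_cluster(seq_len(t), k, matrix)
    rs$provenance$case <- "fallback"
    cands <- list(rs)
  }
  scores <- vapply(cands, function(x) x$score, numeric(1))
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    keys <- vapply(cands[best],
                   function(x) paste(sprintf("%09d", x$indices), collapse = ","),
                   character(1))
    best <- best[order(keys)]
  }
  out <- cands[[best[1]]]
  attr(out, "clusters") <- cs
  attr(out, "candidates") <- cands
  out
}

#' Exhaustive reference selection (exact baseline)
#'
#' Enumerates every k-subset and returns the one minimizing the total
#' candidate count (ties: lexicographically smallest). Used as the test
#' oracle and as an optional exact mode; refuses above `10^6` subsets.
#'
#' @param matrix A [similarity_matrix()].
#' @param k Subset size, `2 <= k <= t`.
#' @return A `reference_set` with provenance case `"exhaustive"`.
#' @export
exhaustive_select <- function(matrix, k) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  t <- matrix$t
  k <- as.integer(k)
  if (k < 2L || k > t) stop("'k' must satisfy 2 <= k <= t", call. = FALSE)
  if (k == t) return(new_reference_set(seq_len(t), matrix, "exhaustive"))
  if (choose(t, k) > 1e6)
    stop("choose(t, k) exceeds 1e6 subsets; use select_references()",
         call. = FALSE)
  subsets <- utils::combn(t, k)
  totals <- apply(subsets, 2L, function(ix) total_candidate_count(ix, matrix))
  best <- which.min(totals)  # combn is lexicographic; first minimum wins
  new_reference_set(subsets[, best], matrix, "exhaustive")
}
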