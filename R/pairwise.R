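# Pairwise aggregation stage: from per-distance candidate counts to the
# sequence-similarity graph. For a sequence pair the raw count
#   N_r(s_i, s_j)  = sum over window pairs of |M_d| at their distance
# drives the final objective, while the weighted count
#   N_r'(s_i, s_j) = sum over window pairs of |M_d| / (d_H + 1)
# amplifies near-duplicate window pairs before clustering. Similarity is
#   sim(s_i, s_j)  = max_{i<j} N_r' / N_r'(s_i, s_j),
# so mutually dissimilar sequences (few shared candidates) attract.

pair_hist <- function(s_i, s_j, table, alphabet = NULL) {
  p <- table$params
  alph <- if (is.null(alphabet)) {
    if (p$sigma == 4L) alphabet_spec("dna")
    else if (p$sigma == 20L) alphabet_spec("protein")
    else alphabet_spec(p$sigma)
  } else alphabet_spec(alphabet)
  x <- if (is.character(s_i)) encode_sequence(s_i, alph, "s_i") else as.integer(s_i)
  y <- if (is.character(s_j)) encode_sequence(s_j, alph, "s_j") else as.integer(s_j)
  if (length(x) != length(y))
    stop("sequences must have equal length", call. = FALSE)
  if (length(x) < p$l) stop("sequences shorter than l", call. = FALSE)
  lmer_dist_histogram_cpp(x, y, p$l)
}

#' Candidate motifs generated by a sequence pair
#'
#' Sums the common candidate-motif count over all `(n-l+1)^2` pairs of
#' l-length windows of the two sequences, via the distance histogram and
#' the precomputed count table (O(n^2) total).
#'
#' @param s_i,s_j Sequences (strings or 0-based code vectors) of equal
#'   length over the table's alphabet.
#' @param table A [build_count_table()] result.
#' @param alphabet Optional alphabet override for character input.
#' @return Non-negative count (double; exact below `2^53`).
#' @export
pair_candidate_count <- function(s_i, s_j, table, alphabet = NULL) {
  stopifnot(inherits(table, "candidate_count_table"))
  sum(pair_hist(s_i, s_j, table, alphabet) * table$counts_full)
}

#' Distance-weighted candidate count for a sequence pair
#'
#' As [pair_candidate_count()], but each window pair contributes
#' `count / (d_H + 1)`, boosting the influence of small-distance (rare,
#' expensive) window pairs on the similarity graph.
#'
#' @inheritParams pair_candidate_count
#' @return Non-negative real.
#' @export
weighted_pair_count <- function(s_i, s_j, table, alphabet = NULL) {
  stopifnot(inherits(table, "candidate_count_table"))
  l <- table$params$l
  sum(pair_hist(s_i, s_j, table, alphabet) * table$counts_full / (0:l + 1))
}

#' Pairwise similarity matrix of a sequence set
#'
#' Computes raw and weighted candidate counts for all `C(t, 2)` sequence
#' pairs and converts the weighted counts into similarities
#' `sim(i, j) = max N_r' / N_r'(i, j)`. The defined minimum similarity is
#' exactly 1, attained at an argmax pair of the weighted counts. If a pair
#' has weighted count zero (possible for tiny `d`), it is capped at the
#' largest finite similarity `max N_r' / min positive N_r'`; if every pair
#' is zero, all similarities are set to 1.
#'
#' The pair list is chunked and may be dispatched over `workers`
#' processes; results land in preassigned slots, so the output is
#' identical for any worker count.
#'
#' @param data A [sequence_set()].
#' @param params A [pms_params()]; `params$sigma` must match the set's
#'   alphabet size.
#' @param workers Number of worker processes (forked; 1 = serial).
#' @return Object of class `similarity_matrix` with symmetric `raw`,
#'   `weighted` and `sim` matrices (structural zero diagonals),
#'   `max_weighted`, `ids`, `t`, `params` and the count `table`.
#' @export
similarity_matrix <- function(data, params, workers = 1L) {
  stopifnot(inherits(data, "sequence_set"), inherits(params, "pms_params"))
  if (data$t < 2L) stop("need t >= 2 sequences", call. = FALSE)
  if (params$sigma != data$alphabet$size)
    stop(sprintf("params alphabet size (%d) does not match data (%d)",
                 params$sigma, data$alphabet$size), call. = FALSE)
  if (params$l > data$n) stop("l exceeds sequence length n", call. = FALSE)
  workers <- max(1L, as.integer(workers))
  table <- build_count_table(params)
  t <- data$t; l <- params$l
  pairs <- which(upper.tri(matrix(0, t, t)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  enc_t <- t(data$enc)  # n x t, one column per sequence
  np <- nrow(pairs)
  chunk_of <- sort(rep_len(seq_len(min(workers * 4L, np)), np))
  idx_chunks <- split(seq_len(np), chunk_of)
  run_chunk <- function(idx) {
    pair_histograms_cpp(enc_t, pairs[idx, 1] - 1L, pairs[idx, 2] - 1L, l)
  }
  hists <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx_chunks, run_chunk, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx_chunks, run_chunk)
  }
  H <- do.call(rbind, hists)  # np x (l+1), rows in pair order
  raw_v <- as.vector(H %*% table$counts_full)
  wt_v <- as.vector(H %*% (table$counts_full / (0:l + 1)))
  max_w <- max(wt_v)
  sim_v <- if (max_w == 0) {
    rep(1, np)
  } else {
    s <- max_w / wt_v
    if (any(wt_v == 0)) s[wt_v == 0] <- max_w / min(wt_v[wt_v > 0])
    s
  }
  fill_sym <- function(v) {
    m <- matrix(0, t, t, dimnames = list(data$ids, data$ids))
    m[cbind(pairs[, 1], pairs[, 2])] <- v
    m[cbind(pairs[, 2], pairs[, 1])] <- v
    m
  }
  structure(list(t = t, ids = data$ids,
                 raw = fill_sym(raw_v),
                 weighted = fill_sym(wt_v),
                 sim = fill_sym(sim_v),
                 max_weighted = max_w,
                 params = params, table = table),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf(
    "similarity_matrix: t = %d, (l, d) = (%d, %d), max weighted count %.4g\n",
    x$t, x$params$l, x$params$d, x$max_weighted))
  invisible(x)
}

#' Total candidate count of a reference set
#'
#' The selection objective: the number of candidate motifs generated by a
#' set of reference sequences is the sum of the raw pair counts over all
#' unordered pairs inside the set.
#'
#' @param indices Distinct 1-based sequence indices, at least two.
#' @param matrix A [similarity_matrix()].
#' @return Non-negative total (double).
#' @export
total_candidate_count <- function(indices, matrix) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  indices <- as.integer(indices)
  if (length(indices) < 2L) stop("need at least 2 indices", call. = FALSE)
  if (anyDuplicated(indices)) stop("indices must be distinct", call. = FALSE)
  if (any(indices < 1L | indices > matrix$t))
    stop("index out of range", call. = FALSE)
  pr <- utils::combn(sort(indices), 2L)
  sum(matrix$raw[cbind(pr[1, ], pr[2, ])])
}

#' Write a similarity matrix as TSV
#'
#' Tab-separated t x t similarity matrix with sequence identifiers as row
#' and column headers, for inspection or for external clustering tools.
#'
#' @param matrix A [similarity_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_similarity_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  df <- data.frame(id = matrix$ids, matrix$sim, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
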