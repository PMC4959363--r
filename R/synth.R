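# Planted (l,d) benchmark generator and evaluation utilities.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a planted (l,d) motif-search dataset
#'
#' Emulates the standard benchmark protocol: draw `t` background sequences
#' of length `n` i.i.d. uniform over the alphabet and a uniform random
#' motif `m` of length `l`; choose `q` of the `t` sequences uniformly
#' without replacement; in each chosen sequence overwrite a uniformly
#' chosen l-window with a motif instance. In `"at_most_d"` mode the
#' instance's mismatch count is uniform on `0..d` (mismatch positions
#' uniform without replacement, substituted characters uniform over the
#' `sigma - 1` alternatives); in `"exact_d"` mode it is exactly `d`.
#' Implants overwrite background, keeping `n` fixed.
#'
#' @param t Number of sequences.
#' @param n Sequence length.
#' @param l Motif length.
#' @param d Maximum (or exact) mismatch count, `0 <= d < l < n`.
#' @param q Number of sequences receiving an implant, `0 < q <= t`.
#' @param alphabet `"dna"`, `"protein"`, or an integer size.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param mode `"at_most_d"` or `"exact_d"`.
#' @return Object of class `planted_dataset`: `data` (a
#'   [sequence_set()]), `motif`, `implants` (data frame of sequence index,
#'   start, instance, distance), and `settings`.
#' @export
generate_planted_dataset <- function(t, n, l, d, q = t, alphabet = "dna",
                                     seed = 1L,
                                     mode = c("at_most_d", "exact_d")) {
  mode <- match.arg(mode)
  t <- as.integer(t); n <- as.integer(n); l <- as.integer(l)
  d <- as.integer(d); q <- as.integer(q)
  if (!(d >= 0L && d < l && l < n))
    stop("need 0 <= d < l < n", call. = FALSE)
  if (!(q >= 1L && q <= t)) stop("need 0 < q <= t", call. = FALSE)
  alph <- alphabet_spec(alphabet)
  sigma <- alph$size
  with_seed(as.integer(seed), {
    enc <- matrix(sample.int(sigma, t * n, replace = TRUE) - 1L, nrow = t)
    motif <- sample.int(sigma, l, replace = TRUE) - 1L
    chosen <- sort(sample.int(t, q))
    implants <- data.frame(seq_index = integer(0), start = integer(0),
                           instance = character(0), distance = integer(0))
    for (i in chosen) {
      nmis <- if (mode == "exact_d") d else sample.int(d + 1L, 1L) - 1L
      inst <- motif
      if (nmis > 0L) {
        pos <- sample.int(l, nmis)
        for (p in pos) {
          alt <- setdiff(0:(sigma - 1L), inst[p])
          inst[p] <- alt[sample.int(sigma - 1L, 1L)]
        }
      }
      start <- sample.int(n - l + 1L, 1L)
      enc[i, start:(start + l - 1L)] <- inst
      implants <- rbind(implants, data.frame(
        seq_index = i, start = start,
        instance = decode_sequence(inst, alph),
        distance = sum(inst != motif)))
    }
    seqs <- apply(enc, 1L, decode_sequence, alph = alph)
    structure(list(
      data = sequence_set(seqs, alphabet = alph),
      motif = decode_sequence(motif, alph),
      implants = implants,
      settings = list(t = t, n = n, l = l, d = d, q = q,
                      sigma = sigma, alphabet = alph$name,
                      seed = as.integer(seed), mode = mode)),
      class = "planted_dataset")
  })
}

#' @export
print.planted_dataset <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "planted_dataset: t = %d, n = %d, (l, d) = (%d, %d), q = %d, %s, %s, seed %d\n",
    s$t, s$n, s$l, s$d, s$q, s$alphabet, s$mode, s$seed))
  invisible(x)
}

#' Candidate-count reduction ratio of a selection
#'
#' Compares the candidate motifs generated by the first `k` input
#' sequences (`N_original`, what a solver would use untouched) with those
#' generated by the selected reference set (`N_improved`). A ratio above 1
#' means the selection reduced the candidate space.
#'
#' @param data A [sequence_set()].
#' @param selected A `reference_set` (or an integer vector of k indices).
#' @param k Reference count; must equal the size of `selected`.
#' @param params A [pms_params()].
#' @param matrix Optional precomputed [similarity_matrix()] for `data`.
#' @return List with `n_original`, `n_improved`, `ratio` (Inf when
#'   `n_improved` is 0 and `n_original` > 0; 1 when both are 0).
#' @export
evaluate_ratio <- function(data, selected, k, params, matrix = NULL) {
  idx <- if (inherits(selected, "reference_set")) selected$indices
         else sort(as.integer(selected))
  k <- as.integer(k)
  if (length(idx) != k) stop("'selected' must have exactly k members",
                             call. = FALSE)
  if (is.null(matrix)) matrix <- similarity_matrix(data, params)
  n_orig <- total_candidate_count(seq_len(k), matrix)
  n_impr <- total_candidate_count(idx, matrix)
  ratio <- if (n_impr > 0) n_orig / n_impr
           else if (n_orig > 0) Inf else 1
  list(n_original = n_orig, n_improved = n_impr, ratio = ratio)
}

#' Brute-force count of candidate motifs common to several l-mers
#'
#' Enumerates every l-length string over the alphabet and counts those
#' within Hamming distance `d` of all supplied l-mers. With one l-mer
#' this is the d-ball volume; with two it is the independent oracle for
#' [common_candidate_count()]; with three it supports checking that the
#' exact joint count and the sum of pairwise counts move in the same
#' direction. Guarded to `sigma^l <= 1e7`.
#'
#' @param lmers Character vector of equal-length strings (or a list of
#'   0-based code vectors).
#' @param d Distance radius.
#' @param alphabet `"dna"`, `"protein"`, or an integer size.
#' @param return_set If `TRUE`, also return the matching strings.
#' @return The exact count (double), or a list `(count, set)` when
#'   `return_set` is `TRUE`.
#' @export
brute_force_common_neighbors <- function(lmers, d, alphabet = "dna",
                                         return_set = FALSE) {
  alph <- alphabet_spec(alphabet)
  sigma <- alph$size
  enc <- if (is.character(lmers)) {
    lapply(lmers, encode_sequence, alph = alph)
  } else lapply(lmers, as.integer)
  l <- length(enc[[1]])
  if (!all(lengths(enc) == l)) stop("l-mers must have equal length", call. = FALSE)
  total_words <- sigma^l
  if (total_words > 1e7)
    stop("sigma^l exceeds 1e7; brute force refused", call. = FALSE)
  count <- 0
  kept <- character(0)
  chunk <- 65536L
  powers <- sigma^(seq_len(l) - 1L)
  for (lo in seq(0, total_words - 1, by = chunk)) {
    ids <- lo:min(lo + chunk - 1, total_words - 1)
    # digits matrix: one row per word, one column per position
    W <- outer(ids, powers, function(a, b) (a %/% b) %% sigma)
    ok <- rep(TRUE, length(ids))
    for (x in enc) {
      dist <- rowSums(W != matrix(x, nrow = length(ids), ncol = l,
                                  byrow = TRUE))
      ok <- ok & dist <= d
      if (!any(ok)) break
    }
    count <- count + sum(ok)
    if (return_set && any(ok))
      kept <- c(kept, apply(W[ok, , drop = FALSE], 1L,
                            decode_sequence, alph = alph))
  }
  if (return_set) list(count = count, set = kept) else count
}
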