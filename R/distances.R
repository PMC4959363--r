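#' All-pairs l-mer Hamming distances for a sequence pair
#'
#' Computes the Hamming distance between every l-length window of `s_i`
#' and every l-length window of `s_j` in O(n^2) total time, instead of the
#' naive O(l n^2). A running match count is carried along each diagonal of
#' the (conceptual) n x n match matrix `M`, where
#' `M[a, b] = min(a, b) - d_H` of the aligned prefixes ending at a and b;
#' the distance of the windows ending at `(a, b)` is
#' `l - (M[a, b] - M[a - l, b - l])`.
#'
#' Windows are indexed by their 1-based start position, so entry `(u, v)`
#' of the matrix output is the distance between `substr(s_i, u, u + l - 1)`
#' and `substr(s_j, v, v + l - 1)`.
#'
#' @param s_i,s_j Character strings of equal length `n`, or 0-based
#'   integer code vectors.
#' @param l Window length, `l <= n`.
#' @param output `"matrix"` for the full `(n-l+1) x (n-l+1)` distance
#'   matrix, or `"histogram"` for the multiset of distances as a length
#'   `l + 1` count vector (named `0..l`) — all the downstream aggregation
#'   needs, in O(n) extra space.
#' @param alphabet Alphabet for character input; `"dna"`, `"protein"`, or
#'   an integer size.
#' @return Integer matrix or named integer histogram.
#' @examples
#' all_lmer_distances("ACGT", "AGGT", 2)
#' @export
all_lmer_distances <- function(s_i, s_j, l,
                               output = c("matrix", "histogram"),
                               alphabet = "dna") {
  output <- match.arg(output)
  alph <- alphabet_spec(alphabet)
  x <- if (is.character(s_i)) encode_sequence(s_i, alph, "s_i") else as.integer(s_i)
  y <- if (is.character(s_j)) encode_sequence(s_j, alph, "s_j") else as.integer(s_j)
  if (length(x) != length(y))
    stop("sequences must have equal length", call. = FALSE)
  l <- as.integer(l)
  if (l < 1L || l > length(x))
    stop("'l' must satisfy 1 <= l <= n", call. = FALSE)
  if (output == "matrix") {
    lmer_dist_matrix_cpp(x, y, l)
  } else {
    h <- lmer_dist_histogram_cpp(x, y, l)
    names(h) <- 0:l
    h
  }
}

#' Match-count matrix for two sequences
#'
#' The full n x n dynamic-programming matrix `M` underlying
#' [all_lmer_distances()]: `M[a, b]` is the number of agreeing positions
#' in the alignment of the prefixes of `s_i` and `s_j` ending at `a` and
#' `b` (length `min(a, b)`). Exposed mainly for testing; the production
#' path never materialises it.
#'
#' @inheritParams all_lmer_distances
#' @return An n x n integer matrix.
#' @export
lmer_match_matrix <- function(s_i, s_j, alphabet = "dna") {
  alph <- alphabet_spec(alphabet)
  x <- if (is.character(s_i)) encode_sequence(s_i, alph, "s_i") else as.integer(s_i)
  y <- if (is.character(s_j)) encode_sequence(s_j, alph, "s_j") else as.integer(s_j)
  if (length(x) != length(y))
    stop("sequences must have equal length", call. = FALSE)
  lmer_match_matrix_cpp(x, y)
}
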