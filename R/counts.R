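# Exact combinatorics of common candidate motifs.
#
# A candidate motif for a pair of l-mers (x, x') is an l-length string y
# with d_H(y, x) <= d and d_H(y, x') <= d. The count of such y depends on
# (l, d, sigma) and on d_H(x, x') only. Classify each position of y:
# at the `dist` positions where x and x' disagree, y can match x (a
# positions), match x' (b positions), or match neither (c positions,
# sigma - 2 choices each); at the l - dist agreeing positions y differs
# from both at m positions (sigma - 1 choices each). Then
#   d_H(y, x)  = b + c + m <= d,   d_H(y, x') = a + c + m <= d,
# and the count is the constrained sum over (a, b, c, m) of
#   dist!/(a! b! c!) * (sigma-2)^c * C(l-dist, m) * (sigma-1)^m.
# Setting 0^0 = 1 keeps sigma = 2 valid. Protein-scale counts exceed
# 2^53, so terms are accumulated exactly (see bignum.R).

common_candidate_count_big <- function(params, dist) {
  l <- params$l; d <- params$d; sigma <- params$sigma
  if (dist > 2L * d) return(big_from_num(0))
  total <- big_from_num(0)
  for (a in 0:dist) {
    for (b in 0:(dist - a)) {
      cc <- dist - a - b
      if (sigma == 2L && cc > 0L) next
      for (m in 0:(l - dist)) {
        if (b + cc + m > d || a + cc + m > d) next
        multinom <- choose(dist, a) * choose(dist - a, b)
        term <- big_mul(big_from_num(multinom),
                        big_from_num(choose(l - dist, m)))
        if (cc > 0L) term <- big_mul(term, big_pow_small(sigma - 2L, cc))
        if (m > 0L)  term <- big_mul(term, big_pow_small(sigma - 1L, m))
        total <- big_add(total, term)
      }
    }
  }
  total
}

#' Number of candidate motifs common to two l-mers
#'
#' Counts the l-length strings over a sigma-letter alphabet lying within
#' Hamming distance `d` of both members of a pair of l-mers at Hamming
#' distance `dist` from each other. The count is zero beyond `dist = 2d`
#' (two radius-d balls cannot intersect further apart) and is computed by
#' exact integer arithmetic; protein-scale values exceed `2^53`, so
#' `as = "character"` returns the full decimal integer.
#'
#' @param params A [pms_params()] object.
#' @param dist Hamming distance between the two l-mers, `0 <= dist <= l`.
#' @param as `"numeric"` (default) for a double, `"character"` for the
#'   exact decimal string.
#' @return The common candidate-motif count.
#' @examples
#' common_candidate_count(pms_params(13, 4, "dna"), 8)   # 70
#' @export
common_candidate_count <- function(params, dist, as = c("numeric", "character")) {
  as <- match.arg(as)
  stopifnot(inherits(params, "pms_params"))
  dist <- as.integer(dist)
  if (length(dist) != 1L || is.na(dist) || dist < 0L || dist > params$l)
    stop("'dist' must satisfy 0 <= dist <= l", call. = FALSE)
  big <- common_candidate_count_big(params, dist)
  if (as == "numeric") big_to_num(big) else big_to_str(big)
}

#' Candidate-count lookup table over all pair distances
#'
#' Precomputes the common candidate-motif count for every Hamming distance
#' `0..2d`; any larger distance maps to zero. Pattern-driven solvers pay
#' O(1) per window pair with this table in hand. Counts are strictly
#' decreasing in the distance.
#'
#' @param params A [pms_params()] object.
#' @return An object of class `candidate_count_table` with components
#'   `params`, `counts` (doubles indexed by distance `0..2d`),
#'   `counts_str` (exact decimal strings), and `counts_full` (length
#'   `l + 1` double vector, zero beyond `2d`, used by the pairwise stage).
#' @examples
#' tab <- build_count_table(pms_params(13, 4, "dna"))
#' tab$counts[1]   # distance 0: the d-ball volume, 66379
#' @export
build_count_table <- function(params) {
  stopifnot(inherits(params, "pms_params"))
  dmax <- min(2L * params$d, params$l)
  bigs <- lapply(0:dmax, function(i) common_candidate_count_big(params, i))
  counts <- vapply(bigs, big_to_num, numeric(1))
  full <- numeric(params$l + 1L)
  full[seq_len(dmax + 1L)] <- counts
  structure(list(params = params,
                 counts = counts,
                 counts_str = vapply(bigs, big_to_str, character(1)),
                 counts_sci2 = vapply(bigs, big_signif2_str, character(1)),
                 counts_full = full),
            class = "candidate_count_table")
}

#' Look up a common candidate-motif count
#'
#' @param table A [build_count_table()] result.
#' @param dist Hamming distance(s); values beyond `2d` return 0.
#' @return Double vector of counts.
#' @export
lookup_count <- function(table, dist) {
  stopifnot(inherits(table, "candidate_count_table"))
  dist <- as.integer(dist)
  if (any(dist < 0L | dist > table$params$l))
    stop("'dist' must lie in [0, l]", call. = FALSE)
  table$counts_full[dist + 1L]
}

#' @export
print.candidate_count_table <- function(x, ...) {
  p <- x$params
  cat(sprintf("Candidate-count table for (l, d) = (%d, %d), |Sigma| = %d\n",
              p$l, p$d, p$sigma))
  df <- data.frame(dist = seq_along(x$counts) - 1L,
                   count = x$counts_str,
                   count_sci = x$counts_sci2,
                   p_i = sprintf("%.1e", pair_probability(
                     p$l, seq_along(x$counts) - 1L, p$sigma)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Probability of a given Hamming distance between random l-mers
#'
#' For two l-mers drawn independently and uniformly over a sigma-letter
#' alphabet, the distance is Binomial(l, (sigma-1)/sigma), so
#' `p_i = C(l, i) (sigma-1)^i / sigma^l`.
#'
#' @param l Word length.
#' @param i Hamming distance(s), each in `0..l`.
#' @param sigma Alphabet size (or `"dna"`/`"protein"`).
#' @return Probability vector, full double precision.
#' @examples
#' pair_probability(13, 8, 4)   # ~0.126
#' @export
pair_probability <- function(l, i, sigma = 4) {
  if (is.character(sigma)) sigma <- alphabet_spec(sigma)$size
  l <- as.integer(l); i <- as.integer(i); sigma <- as.integer(sigma)
  stopifnot(l >= 1L, sigma >= 2L)
  if (any(i < 0L | i > l))
    stop("'i' must lie in [0, l]", call. = FALSE)
  # evaluate in log space so large-l tails keep full relative precision
  exp(lchoose(l, i) + i * log(sigma - 1) - l * log(sigma))
}

#' Expected number of window pairs at a given distance
#'
#' For two length-n sequences there are `(n - l + 1)^2` pairs of l-length
#' windows; the expected number at Hamming distance `i` under a uniform
#' random background is `(n - l + 1)^2 * p_i`. Pairs with expectation
#' below one are the rare, near-duplicate window pairs that blow up
#' candidate generation when they do occur.
#'
#' @inheritParams pair_probability
#' @param n Sequence length, `n >= l`.
#' @return Expected count(s).
#' @export
expected_pair_count <- function(n, l, i, sigma = 4) {
  n <- as.integer(n)
  stopifnot(n >= l)
  (n - l + 1)^2 * pair_probability(l, i, sigma)
}
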