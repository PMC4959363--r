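# Minimal exact non-negative integer arithmetic for candidate-motif counts.
# Protein count tables exceed 2^53, past the range where doubles are exact,
# and no arbitrary-precision package is available, so counts are accumulated
# in little-endian base-1e6 digit vectors. Only the operations the count
# table needs are provided: construct, add, multiply, compare, render.
# Digits are stored as doubles; every intermediate stays well below 2^53
# (digit product <= (1e6-1)^2 * ndigits, carried eagerly).

BIG_BASE <- 1e6

big_norm <- function(v) {
  carry <- 0
  for (i in seq_along(v)) {
    x <- v[i] + carry
    carry <- floor(x / BIG_BASE)
    v[i] <- x - carry * BIG_BASE
  }
  while (carry > 0) {
    v <- c(v, carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  while (length(v) > 1L && v[length(v)] == 0) v <- v[-length(v)]
  v
}

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  v <- numeric(0)
  while (x > 0) {
    v <- c(v, x %% BIG_BASE)
    x <- floor(x / BIG_BASE)
  }
  v
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# Schoolbook product. Un-normalized partial sums are bounded by
# ndigits * (1e6-1)^2, exact in doubles for any count this package meets.
big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    res[idx] <- res[idx] + a[i] * b
  }
  big_norm(res)
}

big_pow_small <- function(base, e) {
  out <- big_from_num(1)
  if (e == 0) return(out)
  b <- big_from_num(base)
  for (i in seq_len(e)) out <- big_mul(out, b)
  out
}

big_cmp <- function(a, b) {
  a <- big_norm(a); b <- big_norm(b)
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

big_to_num <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

big_to_str <- function(a) {
  a <- big_norm(a)
  top <- format(a[length(a)], scientific = FALSE)
  if (length(a) == 1L) return(top)
  paste0(top, paste(sprintf("%06.0f", rev(a[-length(a)])), collapse = ""))
}

# Two-significant-figure scientific rendering ("9.2e+02") straight from the
# digit vector, avoiding any double round-trip for very large counts.
big_signif2_str <- function(a) {
  s <- big_to_str(a)
  if (s == "0") return("0")
  digs <- as.integer(strsplit(s, "")[[1]])
  expo <- length(digs) - 1L
  d1 <- digs[1]; d2 <- if (length(digs) >= 2L) digs[2] else 0L
  rnd <- if (length(digs) >= 3L && digs[3] >= 5L) 1L else 0L
  d2 <- d2 + rnd
  if (d2 == 10L) { d2 <- 0L; d1 <- d1 + 1L }
  if (d1 == 10L) { d1 <- 1L; d2 <- 0L; expo <- expo + 1L }
  sprintf("%d.%de+%02d", d1, d2, expo)
}
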