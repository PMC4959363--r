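#' Planted (l,d) motif-search parameters
#'
#' Bundle of the parameters that define a planted (l,d) motif-search
#' instance: the motif length `l`, the maximum number of mismatches `d`,
#' the alphabet size `sigma` (4 for DNA, 20 for protein, any size >= 2
#' accepted) and, optionally, the sequence length `n` for instances tied
#' to a concrete dataset.
#'
#' @param l Motif length in characters.
#' @param d Maximum number of mismatches allowed between a motif and an
#'   occurrence; must satisfy `0 <= d < l`.
#' @param sigma Alphabet size, an integer >= 2. May also be given as
#'   `"dna"` (4) or `"protein"` (20).
#' @param n Optional sequence length; when supplied, `l < n` is enforced.
#' @return An object of class `pms_params`.
#' @examples
#' pms_params(13, 4, "dna")
#' @export
pms_params <- function(l, d, sigma = 4, n = NULL) {
  if (is.character(sigma)) sigma <- alphabet_spec(sigma)$size
  l <- as.integer(l); d <- as.integer(d); sigma <- as.integer(sigma)
  if (length(l) != 1L || is.na(l) || l < 1L)
    stop("'l' must be a single positive integer", call. = FALSE)
  if (length(d) != 1L || is.na(d) || d < 0L || d >= l)
    stop("'d' must satisfy 0 <= d < l", call. = FALSE)
  if (length(sigma) != 1L || is.na(sigma) || sigma < 2L)
    stop("'sigma' must be an integer >= 2", call. = FALSE)
  if (!is.null(n)) {
    n <- as.integer(n)
    if (length(n) != 1L || is.na(n) || n <= l)
      stop("'n' must satisfy l < n", call. = FALSE)
  }
  structure(list(l = l, d = d, sigma = sigma, n = n), class = "pms_params")
}

#' @export
print.pms_params <- function(x, ...) {
  cat(sprintf("(l, d) = (%d, %d), |Sigma| = %d%s\n", x$l, x$d, x$sigma,
              if (is.null(x$n)) "" else sprintf(", n = %d", x$n)))
  invisible(x)
}

# Alphabet registry. DNA and protein are the named alphabets; an explicit
# letter set or a bare size may be used for anything else.
alphabet_spec <- function(alphabet) {
  if (inherits(alphabet, "refselect_alphabet")) return(alphabet)
  if (is.numeric(alphabet)) {
    size <- as.integer(alphabet)
    if (size < 2L) stop("alphabet size must be >= 2", call. = FALSE)
    letters0 <- if (size <= 26L) LETTERS[seq_len(size)] else
      sprintf("s%d", seq_len(size))
    return(structure(list(name = sprintf("sigma%d", size),
                          letters = letters0, size = size),
                     class = "refselect_alphabet"))
  }
  alphabet <- tolower(as.character(alphabet))
  spec <- switch(alphabet,
    dna = list(name = "dna", letters = c("A", "C", "G", "T"), size = 4L),
    protein = list(name = "protein",
                   letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   size = 20L),
    stop("unknown alphabet '", alphabet, "'; use 'dna', 'protein', ",
         "or an integer size", call. = FALSE))
  structure(spec, class = "refselect_alphabet")
}

# Encode a character string over `alph` as a 0-based integer vector;
# characters outside the alphabet raise an input error naming the record.
encode_sequence <- function(s, alph, label = "sequence") {
  chars <- strsplit(toupper(s), "")[[1]]
  codes <- match(chars, alph$letters) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop(sprintf("%s contains characters outside the %s alphabet: %s",
                 label, alph$name, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  codes
}

decode_sequence <- function(codes, alph) {
  paste(alph$letters[codes + 1L], collapse = "")
}
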