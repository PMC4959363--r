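#' Construct a validated sequence set
#'
#' The input container for the selection pipeline: `t >= 2` equal-length
#' sequences over a declared alphabet, with identifiers. Sequences are
#' uppercased and validated on construction; characters outside the
#' alphabet (including ambiguity codes such as `N` or `X`) are rejected
#' rather than silently substituted, since substitutions would perturb
#' candidate counts invisibly.
#'
#' @param sequences Character vector of sequences.
#' @param ids Identifiers; defaults to `seq1..seqt`.
#' @param alphabet `"dna"`, `"protein"`, `"auto"` (DNA iff every character
#'   is one of A/C/G/T, protein otherwise), or an integer size.
#' @return Object of class `sequence_set` with fields `sequences`, `ids`,
#'   `alphabet`, `t`, `n`, and `enc` (t x n matrix of 0-based codes).
#' @export
sequence_set <- function(sequences, ids = NULL, alphabet = "auto") {
  sequences <- toupper(as.character(sequences))
  t <- length(sequences)
  if (t < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_len(t))
  ids <- as.character(ids)
  stopifnot(length(ids) == t)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf(
      "all sequences must have equal length; record '%s' has length %d, expected %d",
      ids[bad], lens[bad], lens[1]), call. = FALSE)
  }
  n <- lens[1]
  if (n < 1L) stop("empty sequences", call. = FALSE)
  if (identical(alphabet, "auto")) {
    alphabet <- if (grepl("^[ACGT]+$", paste(sequences, collapse = "")))
      "dna" else "protein"
  }
  alph <- alphabet_spec(alphabet)
  enc <- matrix(0L, nrow = t, ncol = n)
  for (i in seq_len(t))
    enc[i, ] <- encode_sequence(sequences[i], alph, sprintf("record '%s'", ids[i]))
  structure(list(sequences = sequences, ids = ids, alphabet = alph,
                 t = t, n = n, enc = enc),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: t = %d sequences of length n = %d (%s)\n",
              x$t, x$n, x$alphabet$name))
  invisible(x)
}

#' Read sequences from FASTA or line-per-sequence text
#'
#' @param path File path.
#' @param format `"fasta"`, `"lines"` (one sequence per line) or `"auto"`
#'   (FASTA iff the first non-empty line starts with `>`).
#' @param alphabet Passed to [sequence_set()].
#' @return A [sequence_set()] whose `format` attribute records the input
#'   format for symmetric writing.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "lines"),
                           alphabet = "auto") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (length(first) == 0L) stop("empty input file: ", path, call. = FALSE)
    format <- if (startsWith(first[1], ">")) "fasta" else "lines"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty input file: ", path, call. = FALSE)
    out <- sequence_set(as.character(set), ids = names(set),
                        alphabet = alphabet)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty input file: ", path, call. = FALSE)
    out <- sequence_set(lines, alphabet = alphabet)
  }
  attr(out, "format") <- format
  out
}

#' Write a sequence set
#'
#' FASTA output is single-line per record with the original header text;
#' `"lines"` output is one bare sequence per line.
#'
#' @param data A [sequence_set()].
#' @param path Output path.
#' @param format `"fasta"` or `"lines"`; defaults to the format the set
#'   was read with, else FASTA.
#' @return Invisibly, `path`.
#' @export
write_sequences <- function(data, path, format = NULL) {
  stopifnot(inherits(data, "sequence_set"))
  if (is.null(format)) format <- attr(data, "format")
  if (is.null(format)) format <- "fasta"
  format <- match.arg(format, c("fasta", "lines"))
  lines <- if (format == "fasta") {
    as.vector(rbind(paste0(">", data$ids), data$sequences))
  } else data$sequences
  writeLines(lines, path)
  invisible(path)
}
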