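#' Run configuration for the selection pipeline
#'
#' Either `k` is given directly, or `(q, h)` from which `k = t - q + h` is
#' derived at run time: a quorum-q solver drawing h-tuples needs
#' `t - q + h` reference sequences to guarantee coverage.
#'
#' @param l,d Motif length and mismatch bound.
#' @param k Reference count; exclusive with `(q, h)`.
#' @param q,h Quorum and tuple size; exclusive with `k`.
#' @param alphabet `"dna"`, `"protein"`, or `"auto"`.
#' @param workers Worker processes for the pairwise stage.
#' @param mode `"cluster"` (MCL + refinement, default) or `"exhaustive"`.
#' @param mcl An [mcl_config()].
#' @param seed Optional integer seed (used only by randomized
#'   subcommands; the selection itself is deterministic).
#' @param quiet Suppress progress messages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(l, d, k = NULL, q = NULL, h = NULL,
                       alphabet = "auto", workers = 1L,
                       mode = c("cluster", "exhaustive"),
                       mcl = mcl_config(), seed = NULL, quiet = TRUE) {
  mode <- match.arg(mode)
  has_k <- !is.null(k); has_qh <- !is.null(q) || !is.null(h)
  if (has_k == has_qh)
    stop("provide exactly one of 'k' or both 'q' and 'h'", call. = FALSE)
  if (has_qh && (is.null(q) || is.null(h)))
    stop("'q' and 'h' must be provided together", call. = FALSE)
  structure(list(l = as.integer(l), d = as.integer(d),
                 k = if (has_k) as.integer(k) else NULL,
                 q = if (has_qh) as.integer(q) else NULL,
                 h = if (has_qh) as.integer(h) else NULL,
                 alphabet = alphabet, workers = as.integer(workers),
                 mode = mode, mcl = mcl,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 quiet = isTRUE(quiet)),
            class = "run_config")
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Select reference sequences and repose them first
#'
#' The end-to-end driver: builds the candidate-count table and the
#' pairwise similarity matrix, selects the k reference sequences
#' (clustered or exhaustive mode), and returns the dataset reordered so
#' the selected sequences come first — in ascending original index,
#' followed by the remaining sequences in their original relative order —
#' together with a run report.
#'
#' @param data A [sequence_set()].
#' @param config A [run_config()].
#' @return List with `data` (reordered [sequence_set()]) and `report`
#'   (input summary, selected indices and identifiers, cluster
#'   diagnostics, totals for the selected and first-k sets, their ratio,
#'   per-stage timings, warnings).
#' @export
run_refselect <- function(data, config) {
  stopifnot(inherits(data, "sequence_set"), inherits(config, "run_config"))
  t <- data$t
  k <- if (!is.null(config$k)) config$k else t - config$q + config$h
  if (!(k > 1L && k < t))
    stop(sprintf("derived k = %d must satisfy 1 < k < t = %d", k, t),
         call. = FALSE)
  params <- pms_params(config$l, config$d, data$alphabet$size, data$n)
  warnings <- character(0)
  timings <- c(pairwise = NA_real_, selection = NA_real_)
  log_stage(config$quiet, "pairwise stage: t = %d, %d pairs", t, choose(t, 2))
  t0 <- proc.time()[["elapsed"]]
  mat <- similarity_matrix(data, params, workers = config$workers)
  timings["pairwise"] <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  sel <- withCallingHandlers(
    if (config$mode == "exhaustive") exhaustive_select(mat, k)
    else select_references(mat, k, config$mcl),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  timings["selection"] <- proc.time()[["elapsed"]] - t0
  log_stage(config$quiet, "selected: %s", paste(sel$indices, collapse = " "))
  ord <- c(sel$indices, setdiff(seq_len(t), sel$indices))
  reordered <- sequence_set(data$sequences[ord], ids = data$ids[ord],
                            alphabet = data$alphabet)
  attr(reordered, "format") <- attr(data, "format")
  ev <- evaluate_ratio(data, sel, k, params, matrix = mat)
  cs <- attr(sel, "clusters")
  report <- list(
    input = list(t = t, n = data$n, alphabet = data$alphabet$name),
    parameters = list(l = params$l, d = params$d, k = k,
                      q = config$q, h = config$h, mode = config$mode,
                      workers = config$workers,
                      inflation = config$mcl$inflation),
    selected = list(indices = sel$indices,
                    ids = data$ids[sel$indices],
                    case = sel$provenance$case,
                    score = sel$score),
    totals = list(selected = ev$n_improved,
                  first_k = ev$n_original,
                  ratio = ev$ratio),
    clusters = if (is.null(cs)) NULL else list(
      membership = cs$clusters, validity = cs$validity,
      converged = cs$converged, iterations = cs$iterations),
    timings = as.list(timings),
    warnings = warnings)
  list(data = reordered, report = report)
}

#' Write pipeline outputs
#'
#' Reordered sequences go out in the input's format (FASTA stays FASTA
#' with original headers); the report is written as JSON.
#'
#' @param data Reordered [sequence_set()] from [run_refselect()].
#' @param report Report list from [run_refselect()].
#' @param out_path Sequence output path.
#' @param report_path JSON report path (skipped if `NULL`).
#' @return Invisibly, `out_path`.
#' @export
write_outputs <- function(data, report, out_path, report_path = NULL) {
  write_sequences(data, out_path)
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(out_path)
}
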