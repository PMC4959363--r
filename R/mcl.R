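#' Markov clustering configuration
#'
#' Controls the MCL iteration on the similarity graph. Defaults follow
#' common MCL practice: inflation 1.8 (coarse-to-medium granularity),
#' expansion by matrix squaring, per-node self-loops equal to the node's
#' maximum incident weight (damping), pruning of vanishing entries, and
#' convergence on the maximum absolute entry change.
#'
#' @param inflation Entrywise power applied between expansions; `> 1`.
#' @param expansion Matrix power per iteration; integer `>= 2`.
#' @param max_iterations Iteration cap.
#' @param convergence_tolerance Stop when the largest absolute entry
#'   change falls below this.
#' @param prune_threshold Entries below this are zeroed after inflation.
#' @return Object of class `mcl_config`.
#' @export
mcl_config <- function(inflation = 1.8, expansion = 2L,
                       max_iterations = 100L,
                       convergence_tolerance = 1e-8,
                       prune_threshold = 1e-14) {
  stopifnot(inflation > 1, expansion >= 2L,
            max_iterations >= 1L,
            convergence_tolerance > 0, prune_threshold > 0)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 max_iterations = as.integer(max_iterations),
                 convergence_tolerance = convergence_tolerance,
                 prune_threshold = prune_threshold),
            class = "mcl_config")
}

normalize_cols <- function(M) {
  cs <- colSums(M)
  dead <- cs == 0
  if (any(dead)) {
    # a column starved by pruning keeps its self-loop
    M[cbind(which(dead), which(dead))] <- 1
    cs[dead] <- 1
  }
  sweep(M, 2L, cs, "/")
}

#' Markov clustering of a similarity graph
#'
#' Runs MCL (alternating expansion and inflation of a column-stochastic
#' flow matrix) on the similarity matrix and extracts a hard partition.
#' Self-loops are set per node to its maximum incident similarity before
#' normalization. Attractors are the nodes with positive diagonal in the
#' limit matrix; overlapping attractor systems are merged, and each
#' remaining node joins the system receiving most of its flow (ties to
#' the lowest attractor index). Clusters with a single node are flagged
#' invalid: such a node has low similarity with everything.
#'
#' @param matrix A [similarity_matrix()] or a plain symmetric non-negative
#'   matrix.
#' @param config An [mcl_config()].
#' @return Object of class `cluster_set`: `clusters` (list of sorted
#'   1-based index vectors, ordered by smallest member), `validity`,
#'   `converged`, `iterations`.
#' @export
mcl_cluster <- function(matrix, config = mcl_config()) {
  stopifnot(inherits(config, "mcl_config"))
  S <- if (inherits(matrix, "similarity_matrix")) matrix$sim else as.matrix(matrix)
  t <- nrow(S)
  if (t < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (!all(is.finite(S)) || any(S < 0))
    stop("similarity entries must be finite and non-negative", call. = FALSE)
  if (max(abs(S - t(S))) > 0) stop("matrix must be symmetric", call. = FALSE)
  A <- S
  diag(A) <- 0
  loop <- apply(A, 1L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- normalize_cols(A)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config$max_iterations)) {
    E <- M
    for (e in seq_len(config$expansion - 1L)) E <- E %*% M
    Inew <- E^config$inflation
    Inew[Inew < config$prune_threshold] <- 0
    Inew <- normalize_cols(Inew)
    delta <- max(abs(Inew - M))
    M <- Inew
    if (delta < config$convergence_tolerance) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", config$max_iterations,
            " iterations; interpreting current matrix", call. = FALSE)
  clusters <- mcl_extract_clusters(M)
  structure(list(clusters = clusters,
                 validity = lengths(clusters) > 1L,
                 converged = converged, iterations = iter),
            class = "cluster_set")
}

# Interpret the MCL limit matrix as a hard partition.
mcl_extract_clusters <- function(M) {
  t <- nrow(M)
  attractors <- which(diag(M) > 0)
  if (length(attractors) == 0L) attractors <- seq_len(t)  # degenerate
  # merge overlapping attractor systems: attractors sharing flow are one
  sys_id <- seq_along(attractors)
  repeat {
    changed <- FALSE
    for (i in seq_along(attractors)) for (j in seq_along(attractors)) {
      if (sys_id[i] != sys_id[j] &&
          (M[attractors[i], attractors[j]] > 0 ||
           M[attractors[j], attractors[i]] > 0)) {
        sys_id[sys_id == max(sys_id[c(i, j)])] <- min(sys_id[c(i, j)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  systems <- split(attractors, sys_id)
  systems <- systems[order(vapply(systems, min, integer(1)))]
  assign <- integer(t)
  for (v in seq_len(t)) {
    w <- vapply(systems, function(s) sum(M[s, v]), numeric(1))
    if (max(w) == 0) {
      assign[v] <- NA_integer_  # isolated: becomes its own cluster
    } else {
      assign[v] <- which(w == max(w))[1]  # ties -> lowest attractor index
    }
  }
  clusters <- lapply(seq_along(systems),
                     function(s) sort(which(!is.na(assign) & assign == s)))
  clusters <- c(clusters, lapply(which(is.na(assign)), identity))
  clusters <- clusters[lengths(clusters) > 0L]
  clusters[order(vapply(clusters, min, integer(1)))]
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (%d valid), %s in %d iterations\n",
              length(x$clusters), sum(x$validity),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  for (i in seq_along(x$clusters))
    cat(sprintf("  [%d]%s %s\n", i, if (x$validity[i]) "" else " (invalid)",
                paste(x$clusters[[i]], collapse = " ")))
  invisible(x)
}
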