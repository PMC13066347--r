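## Signed network propagation on the bipartite sensitivity graph.
## Random-walk-with-restart kernel extended to directed, signed edges,
## with an optional per-iteration clamp that sets any negative node
## weight to zero (full consumption of a metabolite / extinction of a
## species), and a pinned-environment mode in which metabolite nodes
## act as Dirichlet boundary conditions fixed at their seed values.

#' Seed set for propagation
#'
#' @param values named nonnegative numeric, node id -> seed weight.
#' @param mode `"species_seed"` (seeds on species nodes) or
#'   `"environment"` (seeds on metabolite nodes, pinned during
#'   propagation).
#' @return object of class `seed_set`.
#' @export
seed_set <- function(values, mode = c("species_seed", "environment")) {
  mode <- match.arg(mode)
  if (!length(values) || is.null(names(values)))
    csense_error("seeds must be a non-empty named vector",
                 "csense_seed_error")
  if (any(values < 0))
    csense_error("seed values must be >= 0", "csense_seed_error")
  structure(list(values = values, mode = mode), class = "seed_set")
}

#' Normalized signed influence operator
#'
#' Each node's outgoing edge weights are divided by the sum of their
#' absolute values (signs preserved), giving a sub-stochastic signed
#' operator; nodes without out-edges contribute nothing.
#'
#' @param graph a `sensitivity_graph` with at least one edge.
#' @return n x n matrix `P` (rows = source nodes), with
#'   `rowSums(abs(P)) <= 1`.
#' @export
normalize_weights <- function(graph) {
  e <- graph$edges
  if (!nrow(e))
    csense_error("graph has no edges", "csense_parameter_error")
  ids <- graph$nodes$id
  P <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(e)))
    P[e$source_id[i], e$target_id[i]] <-
      P[e$source_id[i], e$target_id[i]] + e$weight[i]
  norm <- rowSums(abs(P))
  nz <- norm > 0
  P[nz, ] <- P[nz, , drop = FALSE] / norm[nz]
  P
}

#' Propagate seed weights to a steady state
#'
#' Iterates `x <- (1 - restart) * t(P) %*% x + restart * s` where `P`
#' is the row-normalized signed operator and `s` the seed vector.  With
#' `clamp = "on"` negative entries are set to zero after each update
#' (and with `absorbing = TRUE` they stay zero).  In environment mode
#' the metabolite nodes are reset to their seed values after each
#' update.  Stops when the L1 change drops below `tol` or after
#' `max_iter` iterations; non-convergence is reported in the returned
#' state, never raised.
#'
#' @param graph a `sensitivity_graph`.
#' @param seeds a [seed_set()]; seed node kinds must match its mode.
#' @param restart restart probability in (0, 1], default 0.3.
#' @param clamp `"on"` (default) or `"off"`.
#' @param tol L1 convergence threshold, default 1e-8.
#' @param max_iter iteration cap, default 10000.
#' @param absorbing if `TRUE`, a clamped node can never recover.
#' @return object of class `propagation_state`: `weights` (named,
#'   all >= 0 when clamped), `iterations`, `converged`,
#'   `residual_history`.
#' @export
propagate <- function(graph, seeds, restart = 0.3,
                      clamp = c("on", "off"), tol = 1e-8,
                      max_iter = 10000L, absorbing = FALSE) {
  clamp <- match.arg(clamp)
  stopifnot(inherits(seeds, "seed_set"))
  if (!is.finite(restart) || restart <= 0 || restart > 1)
    csense_error("restart must be in (0, 1]", "csense_parameter_error")
  ids <- graph$nodes$id
  kind <- stats::setNames(graph$nodes$kind, ids)
  sv <- seeds$values[names(seeds$values) %in% ids]
  if (!length(sv))
    csense_error("no seed node is present in the graph",
                 "csense_seed_error")
  want <- if (seeds$mode == "environment") "metabolite" else "species"
  if (any(kind[names(sv)] != want))
    csense_error(paste0(seeds$mode, " mode seeds must be ", want,
                        " nodes"),
                 "csense_seed_error")

  P <- normalize_weights(graph)
  Pt <- t(P)
  s <- stats::setNames(numeric(length(ids)), ids)
  s[names(sv)] <- sv
  x <- s
  pinned <- if (seeds$mode == "environment") kind == "metabolite"
            else rep(FALSE, length(ids))
  dead <- rep(FALSE, length(ids))
  resid <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    x_new <- as.vector((1 - restart) * (Pt %*% x)) + restart * s
    names(x_new) <- ids
    if (clamp == "on") {
      if (absorbing) {
        dead <- dead | x_new < 0
        x_new[dead] <- 0
      } else {
        x_new[x_new < 0] <- 0
      }
    }
    x_new[pinned] <- s[pinned]
    r <- sum(abs(x_new - x))
    resid <- c(resid, r)
    x <- x_new
    if (r < tol) { converged <- TRUE; break }
  }
  structure(list(weights = x, iterations = it, converged = converged,
                 residual_history = resid, mode = seeds$mode,
                 restart = restart, clamp = clamp,
                 absorbing = absorbing),
            class = "propagation_state")
}

#' @export
print.propagation_state <- function(x, ...) {
  cat("<propagation_state>", length(x$weights), "nodes;",
      x$iterations, "iterations;",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Species-count seeds from an abundance table
#'
#' The `top_n` species by count in the chosen sample get their counts
#' as seed values; everything else is 0.  Ties at the cutoff are broken
#' by lexicographic species id.
#'
#' @param table data.frame with a `sample_id` column and one numeric
#'   column per species (as read from `abundance.tsv`), or a numeric
#'   matrix with sample rownames.
#' @param sample_id sample to use.
#' @param top_n number of species to seed, default 10.
#' @return a species-mode [seed_set()].
#' @export
seed_from_abundance <- function(table, sample_id, top_n = 10L) {
  if (!is_count(top_n, 1))
    csense_error("top_n must be >= 1", "csense_parameter_error")
  if (is.data.frame(table)) {
    if (!"sample_id" %in% names(table))
      csense_error("abundance table needs a sample_id column",
                   "csense_format_error")
    row <- table[table$sample_id == sample_id, , drop = FALSE]
    if (nrow(row) != 1L)
      csense_error(paste0("sample '", sample_id, "' not found"),
                   "csense_lookup_error")
    counts <- unlist(row[setdiff(names(table), "sample_id")])
  } else {
    if (!sample_id %in% rownames(table))
      csense_error(paste0("sample '", sample_id, "' not found"),
                   "csense_lookup_error")
    counts <- table[sample_id, ]
  }
  counts <- stats::setNames(as.numeric(counts), names(counts))
  ord <- order(-counts, names(counts))      # ties: lexicographic id
  keep <- ord[seq_len(min(top_n, length(counts)))]
  seeds <- counts
  seeds[-keep] <- 0
  seed_set(seeds, "species_seed")
}

#' Pinned-environment seeds from metabolite abundances
#'
#' Maps measured features to graph metabolite nodes and renormalizes
#' the mapped relative abundances to sum 1; unmapped features are
#' ignored, features mapping to nodes absent from the graph are dropped
#' with a warning.
#'
#' @param table data.frame, features x samples, first column
#'   `metabolite_id` or `feature_id`.
#' @param sample_id column to use.
#' @param mapping named character, feature id -> metabolite node id;
#'   `NULL` means feature ids are already node ids.
#' @param graph optional `sensitivity_graph` used to validate node
#'   membership.
#' @return an environment-mode [seed_set()].
#' @export
seed_from_environment <- function(table, sample_id, mapping = NULL,
                                  graph = NULL) {
  idcol <- intersect(c("metabolite_id", "feature_id"), names(table))[1]
  if (is.na(idcol))
    csense_error("table needs a metabolite_id or feature_id column",
                 "csense_format_error")
  if (!sample_id %in% names(table))
    csense_error(paste0("sample '", sample_id, "' not found"),
                 "csense_lookup_error")
  ids <- table[[idcol]]
  vals <- stats::setNames(as.numeric(table[[sample_id]]), ids)
  if (!is.null(mapping)) {
    mapped <- names(vals) %in% names(mapping)
    vals <- vals[mapped]
    names(vals) <- mapping[names(vals)]
  }
  if (!is.null(graph)) {
    known <- names(vals) %in%
      graph$nodes$id[graph$nodes$kind == "metabolite"]
    if (any(!known))
      warning(sum(!known), " feature(s) map to nodes absent from the ",
              "graph; ignored")
    vals <- vals[known]
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals) || sum(vals) <= 0)
    csense_error("no feature maps onto a graph metabolite node",
                 "csense_mapping_error")
  seed_set(vals / sum(vals), "environment")
}

#' Write a propagation state as TSV
#'
#' @param state a `propagation_state`.
#' @param graph the graph it was computed on (for node kinds).
#' @param path output TSV.
#' @export
write_state <- function(state, graph, path) {
  kind <- stats::setNames(graph$nodes$kind, graph$nodes$id)
  df <- data.frame(node_id = names(state$weights),
                   kind = kind[names(state$weights)],
                   weight = state$weights,
                   converged = state$converged,
                   iterations = state$iterations)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
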