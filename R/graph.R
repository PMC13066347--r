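## Signed, weighted, directed bipartite species-metabolite graph built
## from significant PRCC coefficients.  Edge direction encodes
## consumption (metabolite -> species, uptake mode) versus production
## (species -> metabolite, secretion mode); edge sign is the PRCC sign,
## negative meaning growth is suppressed as the metabolite becomes more
## available.

#' Assemble the sensitivity graph from GSA results
#'
#' Keeps one edge per (species, metabolite, mode) whose p-value -- or
#' Benjamini-Hochberg adjusted p-value, adjusted within each species'
#' parameter set -- is strictly below `alpha`.
#'
#' @param results list of `sensitivity_result` objects (one per
#'   species).
#' @param alpha significance level in (0, 1); the analysis default is
#'   0.1.
#' @param adjust `"none"` (raw p, default) or `"bh"`.
#' @return object of class `sensitivity_graph` with `nodes`
#'   (data.frame `id`, `kind`), `edges` (data.frame `source_id`,
#'   `target_id`, `species_id`, `metabolite_id`, `mode`, `weight`,
#'   `t_stat`, `p_value`, `p_adj`, `n_samples`), `alpha`, `adjust`.
#' @export
build_graph <- function(results, alpha = 0.1, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  if (!length(results))
    csense_error("results must be non-empty", "csense_parameter_error")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    csense_error("alpha must be in (0, 1)", "csense_parameter_error")
  if (inherits(results, "sensitivity_result")) results <- list(results)

  edges <- list()
  node_sp <- character()
  node_met <- character()
  for (res in results) {
    stopifnot(inherits(res, "sensitivity_result"))
    tab <- res$table
    node_sp <- c(node_sp, res$species_id)
    node_met <- c(node_met, tab$metabolite_id)
    ok <- !is.na(tab$p_value)
    p_adj <- rep(NA_real_, nrow(tab))
    p_adj[ok] <- stats::p.adjust(tab$p_value[ok], method = "BH")
    p_use <- if (adjust == "bh") p_adj else tab$p_value
    keep <- ok & p_use < alpha
    if (!any(keep)) next
    kept <- tab[keep, , drop = FALSE]
    up <- kept$mode == "uptake"
    edges[[length(edges) + 1L]] <- data.frame(
      source_id = ifelse(up, kept$metabolite_id, res$species_id),
      target_id = ifelse(up, res$species_id, kept$metabolite_id),
      species_id = res$species_id,
      metabolite_id = kept$metabolite_id,
      mode = kept$mode,
      weight = kept$prcc,
      t_stat = kept$t_stat,
      p_value = kept$p_value,
      p_adj = p_adj[keep],
      n_samples = res$n_samples)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else empty_edges()
  nodes <- data.frame(
    id = c(unique(node_sp), unique(node_met)),
    kind = c(rep("species", length(unique(node_sp))),
             rep("metabolite", length(unique(node_met)))))
  structure(list(nodes = nodes, edges = edges, alpha = alpha,
                 adjust = adjust),
            class = "sensitivity_graph")
}

#' Construct a sensitivity graph from an edge table
#'
#' Low-level constructor for hand-built graphs; [build_graph()] is the
#' usual entry point.
#'
#' @param edges data.frame with at least `source_id`, `target_id`,
#'   `mode` (`"uptake"`: metabolite -> species; `"secretion"`:
#'   species -> metabolite), `weight`; `p_value` defaults to 0.
#' @param alpha significance level to record.
#' @param adjust adjustment label to record.
#' @return a `sensitivity_graph`.
#' @export
sensitivity_graph <- function(edges, alpha = 0.1, adjust = "none") {
  if (!all(c("source_id", "target_id", "mode", "weight") %in%
           names(edges)))
    csense_error("edges need source_id, target_id, mode, weight",
                 "csense_format_error")
  if (!all(edges$mode %in% c("uptake", "secretion")))
    csense_error("unknown edge mode", "csense_format_error")
  if (anyDuplicated(edges[c("source_id", "target_id", "mode")]))
    csense_error("duplicate (source, target, mode) edge rows",
                 "csense_format_error")
  e <- empty_edges()[seq_len(nrow(edges)), ]
  for (col in names(edges)) if (col %in% names(e)) e[[col]] <- edges[[col]]
  e$species_id <- ifelse(e$mode == "uptake", e$target_id, e$source_id)
  e$metabolite_id <- ifelse(e$mode == "uptake", e$source_id,
                            e$target_id)
  e$p_value[is.na(e$p_value)] <- 0
  rownames(e) <- NULL
  sp <- unique(e$species_id)
  met <- unique(e$metabolite_id)
  structure(list(nodes = data.frame(
                   id = c(sp, met),
                   kind = c(rep("species", length(sp)),
                            rep("metabolite", length(met)))),
                 edges = e, alpha = alpha, adjust = adjust),
            class = "sensitivity_graph")
}

empty_edges <- function() {
  data.frame(source_id = character(), target_id = character(),
             species_id = character(), metabolite_id = character(),
             mode = character(), weight = numeric(),
             t_stat = numeric(), p_value = numeric(),
             p_adj = numeric(), n_samples = integer())
}

#' @export
print.sensitivity_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat("<sensitivity_graph>", s$n_species, "species,", s$n_metabolites,
      "metabolites,", s$n_edges, "edges (", s$n_negative, "negative),",
      "alpha =", x$alpha, "\n")
  invisible(x)
}

#' Write / read the edge table
#'
#' Tab-separated round trip; weights and statistics are serialized at
#' 12 significant digits.  Node kinds are re-derived from the `mode`
#' column on read.
#'
#' @param graph a `sensitivity_graph`.
#' @param path TSV file path.
#' @export
write_edges <- function(graph, path) {
  e <- graph$edges
  e$kind_source <- ifelse(e$mode == "uptake", "metabolite", "species")
  e$kind_target <- ifelse(e$mode == "uptake", "species", "metabolite")
  for (col in c("weight", "t_stat", "p_value", "p_adj"))
    e[[col]] <- signif(e[[col]], 12)
  hdr <- c("source_id", "target_id", "kind_source", "kind_target",
           "species_id", "metabolite_id", "mode", "weight", "t_stat",
           "p_value", "p_adj", "n_samples")
  utils::write.table(e[hdr], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(path, "alpha") <- graph$alpha
  invisible(path)
}

#' @rdname write_edges
#' @param alpha,adjust significance settings to record on the read
#'   graph (not stored in the TSV).
#' @export
read_edges <- function(path, alpha = 0.1, adjust = "none") {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if ("n_samples" %in% names(e))
    e$n_samples <- as.integer(e$n_samples)
  need <- c("source_id", "target_id", "mode", "weight", "p_value")
  miss <- setdiff(need, names(e))
  if (length(miss))
    csense_error(paste0("edge file missing column(s): ",
                        paste(miss, collapse = ", ")),
                 "csense_format_error")
  if (nrow(e) && !all(e$mode %in% c("uptake", "secretion")))
    csense_error("unknown edge mode", "csense_format_error")
  if (nrow(e) && "kind_source" %in% names(e) &&
      !all(e$kind_source %in% c("species", "metabolite")))
    csense_error("unknown node kind", "csense_format_error")
  if (anyDuplicated(e[c("source_id", "target_id", "mode")]))
    csense_error("duplicate (source, target, mode) edge rows",
                 "csense_format_error")
  if (!"species_id" %in% names(e))
    e$species_id <- ifelse(e$mode == "uptake", e$target_id, e$source_id)
  if (!"metabolite_id" %in% names(e))
    e$metabolite_id <- ifelse(e$mode == "uptake", e$source_id,
                              e$target_id)
  if (!"t_stat" %in% names(e)) e$t_stat <- NA_real_
  if (!"p_adj" %in% names(e)) e$p_adj <- NA_real_
  if (!"n_samples" %in% names(e)) e$n_samples <- NA_integer_
  sp <- unique(e$species_id)
  met <- unique(e$metabolite_id)
  nodes <- data.frame(id = c(sp, met),
                      kind = c(rep("species", length(sp)),
                               rep("metabolite", length(met))))
  cols <- names(empty_edges())
  structure(list(nodes = nodes, edges = e[cols], alpha = alpha,
                 adjust = adjust),
            class = "sensitivity_graph")
}

#' Summary counts of a sensitivity graph
#'
#' @param graph a `sensitivity_graph`.
#' @param breaks histogram breaks over the weight range `[-1, 1]`.
#' @return list with `n_species`, `n_metabolites`, `n_edges`,
#'   `n_negative`, and `weight_histogram` (named counts).
#' @export
graph_summary <- function(graph, breaks = seq(-1, 1, by = 0.25)) {
  e <- graph$edges
  h <- table(cut(e$weight, breaks = breaks, include.lowest = TRUE))
  list(n_species = sum(graph$nodes$kind == "species"),
       n_metabolites = sum(graph$nodes$kind == "metabolite"),
       n_edges = nrow(e),
       n_negative = sum(e$weight < 0),
       weight_histogram = h)
}
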