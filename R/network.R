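#' Pairwise Pearson correlations between gene profiles
#'
#' Correlates the 24-point feature-scaled profiles of the requested genes.
#' Constant genes have undefined correlation and are dropped with a
#' warning.
#'
#' @param mat Feature-scaled gene x 24 matrix.
#' @param genes Genes to include (default: all rows).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(mat, genes = rownames(mat)) {
  if (is.null(rownames(mat))) stop("'mat' must have gene row names")
  miss <- setdiff(genes, rownames(mat))
  if (length(miss)) stop("gene(s) not in matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  sub <- mat[genes, , drop = FALSE]
  const <- apply(sub, 1, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("dropping ", sum(const), " constant gene(s) with undefined correlation")
    sub <- sub[!const, , drop = FALSE]
  }
  if (nrow(sub) < 2) stop("need at least two non-constant genes")
  r <- stats::cor(t(sub))
  diag(r) <- 1
  r
}

#' Build the thresholded coexpression graph over cyclic genes
#'
#' Connects gene pairs whose Pearson correlation is at least `threshold`
#' (one-sided: strong anti-correlation does not create an edge). Nodes are
#' the cyclic genes present in the correlation matrix, annotated with their
#' peak label and peak phase (light for L-labels, dark for D-labels).
#'
#' @param correlations Symmetric correlation matrix ([pearson_matrix()]).
#' @param calls A `"rhythm_calls"` data frame; only `is_cyclic` genes enter
#'   the graph.
#' @param threshold Inclusive correlation cutoff.
#' @return An undirected [igraph][igraph::igraph-package] graph with vertex
#'   attributes `peak_label`, `phase`, edge attribute `weight` (= r) and
#'   graph attribute `threshold`.
#' @export
build_graph <- function(correlations, calls, threshold = 0.90) {
  if (!inherits(calls, "rhythm_calls")) stop("'calls' must come from classify_rhythms()")
  cyc <- calls$gene[calls$is_cyclic]
  nodes <- intersect(rownames(correlations), cyc)
  if (!length(nodes)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    r <- correlations[nodes, nodes, drop = FALSE]
    adj <- (r >= threshold)
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    if (igraph::ecount(g)) igraph::E(g)$weight <- r[igraph::as_edgelist(g, names = TRUE)]
    lab <- calls$peak_label[match(nodes, calls$gene)]
    igraph::V(g)$peak_label <- lab
    igraph::V(g)$phase <- label_phase(lab)
  }
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Connected components of the coexpression graph
#'
#' Components of two or more genes are reported largest first, each
#' labelled with the majority peak phase of its members; degree-zero
#' (isolated) cyclic genes — typically those falling just under the
#' correlation cutoff against every partner — are listed separately.
#'
#' @param graph Output of [build_graph()].
#' @return List with
#'   \describe{
#'     \item{components}{data frame `component`, `size`, `phase`
#'       (majority vote; ties labelled "mixed"), `n_light`, `n_dark`,
#'       sorted by decreasing size}
#'     \item{membership}{named vector mapping each non-isolated gene to its
#'       component id}
#'     \item{isolated}{character vector of degree-zero genes}
#'   }
#' @export
graph_components <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0)
    return(list(components = data.frame(component = integer(0), size = integer(0),
                                        phase = character(0), n_light = integer(0),
                                        n_dark = integer(0)),
                membership = stats::setNames(integer(0), character(0)),
                isolated = character(0)))
  deg <- igraph::degree(graph)
  isolated <- igraph::V(graph)$name[deg == 0]
  sub <- igraph::delete_vertices(graph, which(deg == 0))
  comp <- igraph::components(sub)
  if (comp$no == 0) {
    components <- data.frame(component = integer(0), size = integer(0),
                             phase = character(0), n_light = integer(0),
                             n_dark = integer(0))
    membership <- stats::setNames(integer(0), character(0))
  } else {
    phase <- igraph::V(sub)$phase
    n_light <- tapply(phase == "light", comp$membership, sum)
    n_dark <- tapply(phase == "dark", comp$membership, sum)
    components <- data.frame(
      component = seq_len(comp$no),
      size = as.integer(comp$csize),
      phase = ifelse(n_light > n_dark, "light", ifelse(n_dark > n_light, "dark", "mixed")),
      n_light = as.integer(n_light), n_dark = as.integer(n_dark)
    )
    ord <- order(-components$size, components$component)
    components <- components[ord, , drop = FALSE]
    relabel <- match(seq_len(comp$no), components$component)
    components$component <- seq_len(nrow(components))
    rownames(components) <- NULL
    membership <- stats::setNames(relabel[comp$membership], igraph::V(sub)$name)
  }
  list(components = components, membership = membership, isolated = isolated)
}

#' Write a coexpression graph's edge list as TSV
#'
#' @param graph Output of [build_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   r = if (igraph::ecount(graph)) igraph::E(graph)$weight else numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coexpression graph as GraphML
#'
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
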