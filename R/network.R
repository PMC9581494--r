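#' Interaction network constructor
#'
#' Internal representation of an undirected, simple protein-interaction
#' network: a gene vector and an edge index matrix. Any confidence
#' scores in the source file are discarded; every edge carries a
#' template weight of 1 before sample-specific weighting.
#'
#' @param genes Character vector of node gene symbols (uppercased).
#' @param edges Two-column integer matrix of node indices, one row per
#'   undirected edge, each row ordered (low, high), no duplicates or
#'   self-loops.
#' @return An object of class `interaction_network`.
#' @keywords internal
interaction_network <- function(genes, edges) {
  stopifnot(is.character(genes), is.matrix(edges), ncol(edges) == 2)
  structure(list(genes = genes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", length(x$genes), "genes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read a protein-interaction edge list
#'
#' Parses a STRING/HINT-style tab-separated edge list (two gene columns,
#' optional confidence score column) into a simple undirected network.
#' Gene symbols are uppercased; duplicate edges (in either orientation)
#' are collapsed; self-loops are dropped and counted; confidence scores
#' are discarded and every edge gets template weight 1. A header line is
#' auto-detected from common column names.
#'
#' @param path Path to the TSV edge list.
#' @return An `interaction_network`; attribute `n_self_loops` counts
#'   dropped self-loops.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  if (length(readLines(path, n = 1)) == 0L) {
    stop("edge list is empty: no edges")
  }
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) {
    stop("edge list must have at least two gene columns")
  }
  header_names <- c("gene_a", "gene_b", "gene1", "gene2", "protein1",
                    "protein2", "node1", "node2", "from", "to", "source",
                    "target", "score", "combined_score", "confidence")
  first <- tolower(as.character(tab[1, ]))
  if (any(first %in% header_names)) tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) stop("edge list contains no edges")
  a <- toupper(as.character(tab[[1]]))
  b <- toupper(as.character(tab[[2]]))
  loops <- a == b
  a <- a[!loops]; b <- b[!loops]
  if (length(a) == 0L) stop("edge list contains no edges after ",
                            "dropping self-loops")
  genes <- sort(unique(c(a, b)))
  i <- match(a, genes); j <- match(b, genes)
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  net <- interaction_network(genes, cbind(lo, hi)[keep, , drop = FALSE])
  attr(net, "n_self_loops") <- sum(loops)
  net
}

#' Convert an igraph graph to an interaction network
#' @param g An undirected `igraph` graph with a `name` vertex attribute.
#' @return An `interaction_network`.
#' @export
as_interaction_network <- function(g) {
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  genes <- igraph::vertex_attr(g, "name")
  if (is.null(genes)) genes <- as.character(seq_len(igraph::vcount(g)))
  genes <- toupper(genes)
  e <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(e) <- "integer"
  interaction_network(genes, cbind(pmin(e[, 1], e[, 2]),
                                   pmax(e[, 1], e[, 2])))
}

#' Convert an interaction network to igraph
#' @param net An `interaction_network`.
#' @return An undirected `igraph` graph with vertex names.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$genes)
  igraph::add_edges(g, t(net$edges))
}

#' Per-sample edge weights from perturbation scores
#'
#' Maps one sample's gene perturbation scores onto the network edges.
#' Three schemes are supported: `sum` (default), the absolute sum
#' `|PS_x + PS_y|` of the two endpoint scores; `max`, the larger of the
#' two; and `threshold`, the absolute sum unless either endpoint exceeds
#' `tau`, in which case the interaction is considered dead (weight 0) —
#' modelling complete loss of a binding partner.
#'
#' @param ps_column Named numeric vector of perturbation scores covering
#'   every network gene (gene -> PS), or a single-column slice of the
#'   matrix from [build_ps_matrix()].
#' @param network An `interaction_network`.
#' @param scheme One of `"sum"`, `"max"`, `"threshold"`.
#' @param tau Dead-edge threshold for the `threshold` scheme
#'   (default 0.7).
#' @return Numeric vector of non-negative edge weights, one per network
#'   edge.
#' @export
sample_edge_weights <- function(ps_column, network,
                                scheme = c("sum", "max", "threshold"),
                                tau = 0.7) {
  scheme <- match.arg(scheme)
  ps <- ps_column[network$genes]
  if (anyNA(ps)) {
    stop("perturbation scores missing for network gene(s): ",
         network$genes[which(is.na(ps))[1]])
  }
  x <- ps[network$edges[, 1]]
  y <- ps[network$edges[, 2]]
  w <- switch(scheme,
              sum = abs(x + y),
              max = pmax(x, y),
              threshold = ifelse(x > tau | y > tau, 0, abs(x + y)))
  unname(w)
}

#' Average per-sample edge weights into a cohort graph
#'
#' Averages the per-sample edge weight vectors of one group (all cases
#' or all controls) arithmetically, edge by edge, producing the cohort
#' graph for that group. Case and control cohort graphs always share the
#' template's edge set: edges whose averaged weight is 0 are kept (they
#' contribute nothing to the Laplacian but preserve the common
#' topology).
#'
#' @param weights Numeric matrix, edges x samples: column `s` is
#'   [sample_edge_weights()] for sample `s`. A single vector is treated
#'   as a one-sample group.
#' @param network The shared `interaction_network`.
#' @param label `"case"` or `"control"`.
#' @return An object of class `cohort_graph`: list with `network`,
#'   `weights` (numeric per edge) and `label`.
#' @export
average_cohort_graph <- function(weights, network,
                                 label = c("case", "control")) {
  label <- match.arg(label)
  if (is.null(dim(weights))) weights <- matrix(weights, ncol = 1)
  if (ncol(weights) == 0L) stop("empty group: no samples to average")
  if (nrow(weights) != nrow(network$edges)) {
    stop("weight rows must match the network edge count")
  }
  structure(list(network = network,
                 weights = unname(rowMeans(weights)),
                 label = label),
            class = "cohort_graph")
}

#' @export
print.cohort_graph <- function(x, ...) {
  cat("Cohort graph (", x$label, "): ", length(x$network$genes),
      " genes, ", nrow(x$network$edges), " edges, mean weight ",
      signif(mean(x$weights), 4), "\n", sep = "")
  invisible(x)
}

#' Write a cohort graph as a weighted edge list
#' @param graph A `cohort_graph`.
#' @param path Output TSV path (gene_a, gene_b, weight).
#' @return `path`, invisibly.
#' @export
write_cohort_graph <- function(graph, path) {
  utils::write.table(
    data.frame(gene_a = graph$network$genes[graph$network$edges[, 1]],
               gene_b = graph$network$genes[graph$network$edges[, 2]],
               weight = graph$weights),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Build case and control cohort graphs from a PS matrix in one pass.
# Vectorized over samples: E x S weight matrices per group.
build_cohort_graphs <- function(ps, phenotypes, network,
                                scheme = "sum", tau = 0.7) {
  edge_w <- function(cols) {
    x <- ps[network$edges[, 1], cols, drop = FALSE]
    y <- ps[network$edges[, 2], cols, drop = FALSE]
    switch(scheme,
           sum = abs(x + y),
           max = pmax(x, y),
           threshold = {
             w <- abs(x + y)
             w[x > tau | y > tau] <- 0
             w
           },
           stop("unknown weighting scheme: ", scheme))
  }
  cases <- names(phenotypes)[phenotypes == "case"]
  ctrls <- names(phenotypes)[phenotypes == "control"]
  if (length(cases) == 0L || length(ctrls) == 0L) {
    stop("both a case group and a control group are required")
  }
  list(case = average_cohort_graph(edge_w(cases), network, "case"),
       control = average_cohort_graph(edge_w(ctrls), network, "control"))
}
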