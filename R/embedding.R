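#' Embedding configuration
#'
#' Parameters of the spectral graph wavelet embedding. Wavelet scales
#' can be given explicitly or selected automatically from the spectrum
#' (see [auto_scales()]); the empirical characteristic function is
#' sampled on an evenly spaced grid starting at 0.
#'
#' @param J Number of wavelet scales when scales are automatic
#'   (default 2).
#' @param d Number of characteristic-function sample points
#'   (default 50).
#' @param t_max Upper end of the sampling grid `[0, t_max]`
#'   (default 100).
#' @param eta Pair `(eta_max, eta_min)` controlling automatic scale
#'   selection, `0 < eta_min < eta_max < 1` (default `c(0.95, 0.80)`).
#' @param scales Optional explicit scale vector; overrides automatic
#'   selection.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(J = 2, d = 50, t_max = 100,
                             eta = c(0.95, 0.80), scales = NULL) {
  stopifnot(J >= 1, d >= 2, t_max > 0,
            length(eta) == 2, eta[1] > eta[2], eta[2] > 0, eta[1] < 1)
  if (!is.null(scales)) stopifnot(all(scales > 0))
  structure(list(J = as.integer(J), d = as.integer(d), t_max = t_max,
                 eta = eta, scales = scales),
            class = "embedding_config")
}

#' Spectral decomposition of the weighted graph Laplacian
#'
#' Forms the weighted adjacency matrix `A` and degree matrix `D` of a
#' cohort graph and returns the full symmetric eigendecomposition of the
#' Laplacian `L = D - A`, eigenvalues in ascending order. The smallest
#' eigenvalue of each connected component is 0 (with a constant
#' eigenvector on that component).
#'
#' @param graph A `cohort_graph`, or a list with elements `network` and
#'   `weights` of matching length.
#' @return List of class `spectral_decomposition` with `values`
#'   (ascending eigenvalues) and `vectors` (orthonormal columns).
#' @export
weighted_laplacian <- function(graph) {
  net <- graph$network
  w <- graph$weights
  if (any(!is.finite(w))) stop("non-finite edge weights")
  n <- length(net$genes)
  A <- matrix(0, n, n)
  idx <- net$edges
  A[idx] <- w
  A[idx[, c(2, 1), drop = FALSE]] <- w
  L <- diag(rowSums(A)) - A
  e <- eigen(L, symmetric = TRUE)
  structure(list(values = rev(e$values), vectors = e$vectors[, n:1,
                                                             drop = FALSE]),
            class = "spectral_decomposition")
}

#' Automatic wavelet scale selection
#'
#' Chooses diffusion scales from the Laplacian spectrum so the heat
#' kernel covers neighborhood radii between a tight and a wide limit:
#' `s(eta) = -log(eta) / sqrt(lambda_2 * lambda_N)`, with `J` scales
#' evenly spaced between `s(eta_max)` and `s(eta_min)`. This is the
#' published heuristic of the structural embedding algorithm the method
#' builds on.
#'
#' The smallest eigenvalue used is the smallest *positive* one: on a
#' topologically connected component it is the algebraic connectivity
#' `lambda_2`, but when averaged cohort weights leave some edges at
#' exactly 0 (sparse cohorts) the weighted graph can decouple even
#' though the shared topology does not, and the spectral range of the
#' non-null spectrum remains the right scale reference.
#'
#' @param decomp A `spectral_decomposition` of a connected graph.
#' @param eta Pair `(eta_max, eta_min)`.
#' @param J Number of scales; `J = 1` returns the midpoint of the range.
#' @return Numeric vector of `J` positive scales, increasing.
#' @export
auto_scales <- function(decomp, eta = c(0.95, 0.80), J = 2) {
  lam <- decomp$values
  n <- length(lam)
  if (n < 2) stop("need at least 2 nodes for scale selection")
  lam_max <- lam[n]
  tol <- max(lam_max, 1) * 1e-9
  pos <- lam[lam > tol]
  if (length(pos) == 0L) {
    stop("Laplacian spectrum is all zero (no positive edge weights): ",
         "cannot select diffusion scales")
  }
  geo <- sqrt(pos[1] * lam_max)
  s_lo <- -log(eta[1]) / geo
  s_hi <- -log(eta[2]) / geo
  if (J == 1) return((s_lo + s_hi) / 2)
  seq(s_lo, s_hi, length.out = J)
}

#' Heat-kernel spectral graph wavelets
#'
#' Computes the wavelet matrix `Psi = V diag(exp(-s * lambda)) V^T` at
#' one diffusion scale `s`. Column `a` is the wavelet centred on node
#' `a` (the heat-diffusion pattern seeded there); entry `(m, a)` is the
#' signal node `a` receives from node `m`. `Psi` is symmetric, and on a
#' connected graph every column sums to 1 (diffusion conserves mass).
#' The construction is invariant to eigenvector sign choices since only
#' products `V_mi V_ai` enter.
#'
#' @param decomp A `spectral_decomposition`.
#' @param s Positive diffusion scale.
#' @return The N x N wavelet matrix.
#' @export
heat_wavelets <- function(decomp, s) {
  stopifnot(s > 0)
  V <- decomp$vectors
  g <- exp(-s * pmax(decomp$values, 0))
  Psi <- V %*% (g * t(V))
  (Psi + t(Psi)) / 2
}

#' Characteristic-function node embedding
#'
#' Summarizes each node's wavelet coefficient distribution by its
#' empirical characteristic function
#' \deqn{\phi_a(t) = \frac{1}{N}\sum_m e^{i t \Psi_{ma}}}
#' sampled on `t_grid`, concatenating real and imaginary parts across
#' sample points and then across scales. At `t = 0` the pair is always
#' (1, 0), and `|phi| <= 1` everywhere.
#'
#' @param wavelets A single wavelet matrix or a list of them (one per
#'   scale).
#' @param t_grid Increasing numeric grid starting at 0.
#' @return Numeric matrix, nodes x `2 * length(t_grid) * n_scales`;
#'   columns ordered `Re(t_1), Im(t_1), ..., Re(t_d), Im(t_d)` per
#'   scale. Row names follow the wavelet matrix.
#' @export
characteristic_embedding <- function(wavelets, t_grid) {
  if (is.matrix(wavelets)) wavelets <- list(wavelets)
  stopifnot(length(t_grid) >= 1, t_grid[1] == 0,
            !is.unsorted(t_grid, strictly = TRUE))
  n <- nrow(wavelets[[1]])
  blocks <- lapply(wavelets, function(Psi) {
    out <- matrix(0, n, 2L * length(t_grid))
    for (j in seq_along(t_grid)) {
      tp <- t_grid[j] * Psi
      out[, 2L * j - 1L] <- colMeans(cos(tp))
      out[, 2L * j] <- colMeans(sin(tp))
    }
    out
  })
  emb <- do.call(cbind, blocks)
  rownames(emb) <- rownames(wavelets[[1]])
  emb
}

#' Embed a cohort graph
#'
#' Full embedding pipeline for one weighted graph: Laplacian
#' eigendecomposition, scale selection (unless `scales` is supplied),
#' heat-kernel wavelets at each scale, and the characteristic-function
#' embedding. The graph must be connected as weighted (use
#' [graph_components()] and embed per component otherwise).
#'
#' @param graph A `cohort_graph`.
#' @param config An [embedding_config()].
#' @param scales Optional externally fixed scales — used to embed the
#'   control graph with the scales selected on the case graph so the
#'   two feature spaces are directly comparable.
#' @return Node x feature embedding matrix with attribute `scales`.
#' @export
embed_graph <- function(graph, config = embedding_config(),
                        scales = NULL) {
  decomp <- weighted_laplacian(graph)
  if (is.null(scales)) {
    scales <- if (!is.null(config$scales)) config$scales
              else auto_scales(decomp, config$eta, config$J)
  }
  t_grid <- seq(0, config$t_max, length.out = config$d)
  wl <- lapply(scales, function(s) heat_wavelets(decomp, s))
  emb <- characteristic_embedding(wl, t_grid)
  rownames(emb) <- graph$network$genes
  attr(emb, "scales") <- scales
  emb
}

#' Connected components of an interaction network
#'
#' Splits the (topological) network into connected components and
#' reports which are large enough to embed. Wavelet normalization is
#' per-component, so the analysis runs separately on each component
#' with at least `min_size` nodes; smaller components are excluded and
#' reported.
#'
#' @param network An `interaction_network`.
#' @param min_size Minimum component size to retain (default 3).
#' @return List with `membership` (integer per gene), `keep` (component
#'   ids retained) and `excluded_genes`.
#' @export
graph_components <- function(network, min_size = 3) {
  g <- as_igraph(network)
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_size)
  list(membership = comp$membership,
       keep = keep,
       excluded_genes = network$genes[!comp$membership %in% keep])
}

# Restrict a cohort graph to one component's induced subgraph.
subset_cohort_graph <- function(graph, gene_idx) {
  net <- graph$network
  keep_edge <- net$edges[, 1] %in% gene_idx & net$edges[, 2] %in% gene_idx
  remap <- match(seq_along(net$genes), gene_idx)
  e <- net$edges[keep_edge, , drop = FALSE]
  sub <- interaction_network(net$genes[gene_idx],
                             cbind(remap[e[, 1]], remap[e[, 2]]))
  structure(list(network = sub,
                 weights = graph$weights[keep_edge],
                 label = graph$label),
            class = "cohort_graph")
}

# Embed paired case/control graphs component-wise with shared scales
# (selected on the case graph). Returns stacked embeddings over all
# retained genes, in template gene order, plus the per-component scales.
embed_cohort_pair <- function(case_graph, control_graph,
                              config = embedding_config(),
                              min_component = 3) {
  net <- case_graph$network
  comps <- graph_components(net, min_size = min_component)
  if (length(comps$keep) == 0L) {
    stop("no connected component with at least ", min_component,
         " nodes")
  }
  n_feat <- 2L * config$d *
    (if (!is.null(config$scales)) length(config$scales) else config$J)
  genes_kept <- which(comps$membership %in% comps$keep)
  emb_case <- matrix(NA_real_, length(genes_kept), n_feat,
                     dimnames = list(net$genes[genes_kept], NULL))
  emb_ctrl <- emb_case
  scale_list <- list()
  for (cid in comps$keep) {
    idx <- which(comps$membership == cid)
    gc_case <- subset_cohort_graph(case_graph, idx)
    gc_ctrl <- subset_cohort_graph(control_graph, idx)
    e_case <- embed_graph(gc_case, config)
    e_ctrl <- embed_graph(gc_ctrl, config,
                          scales = attr(e_case, "scales"))
    rows <- match(net$genes[idx], rownames(emb_case))
    emb_case[rows, ] <- e_case
    emb_ctrl[rows, ] <- e_ctrl
    scale_list[[as.character(cid)]] <- attr(e_case, "scales")
  }
  list(case = emb_case, control = emb_ctrl, scales = scale_list,
       excluded_genes = comps$excluded_genes)
}
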