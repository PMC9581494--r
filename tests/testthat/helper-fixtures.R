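# Small graph and cohort fixtures, built in code.

edge_mat <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

make_net <- function(n, edges, genes = sprintf("N%02d", seq_len(n))) {
  perturbnet:::interaction_network(genes, edges)
}

make_graph <- function(net, weights = rep(1, nrow(net$edges)),
                       label = "case") {
  structure(list(network = net, weights = weights, label = label),
            class = "cohort_graph")
}

path_net <- function(n) make_net(n, edge_mat(rbind(1:(n - 1), 2:n)))

star_net <- function(n_leaves) {
  make_net(n_leaves + 1,
           edge_mat(rbind(rep(1, n_leaves), 2:(n_leaves + 1))))
}

# Two k-cliques bridged by one edge between node 1 and node k + 1.
barbell_net <- function(k = 4) {
  cl <- t(utils::combn(k, 2))
  make_net(2 * k, rbind(cl, cl + k, matrix(c(1, k + 1), 1, 2)))
}

# Random connected weighted graph: random spanning tree plus extra
# random edges, weights uniform on [0.1, 2].
random_connected_graph <- function(n, seed) {
  set.seed(seed)
  perm <- sample(n)
  tree <- cbind(perm[-n], perm[-1])
  extra <- ceiling(n / 2)
  more <- cbind(sample(n, extra, replace = TRUE),
                sample(n, extra, replace = TRUE))
  e <- rbind(tree, more)
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(e), , drop = FALSE]
  net <- make_net(n, e)
  make_graph(net, weights = stats::runif(nrow(e), 0.1, 2))
}

# Tiny variant table on disk.
write_tmp_variants <- function(lines, header =
                                 "sample_id\tgene\tzygosity\tvis") {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(header, lines), tf)
  tf
}

# Small simulated study used by several pipeline tests.
small_sim <- function(seed = 11, ...) {
  cfg <- simulation_config(n_genes = 150, module_size = 12,
                           n_case = 60, n_ctrl = 60, seed = seed, ...)
  net <- simulate_network(cfg)
  coh <- simulate_cohort(net$network, net$module, cfg)
  list(cfg = cfg, net = net, coh = coh)
}
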