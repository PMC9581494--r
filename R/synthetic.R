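#' Synthetic cohort simulation configuration
#'
#' Defines the generative model for a synthetic case-control cohort on
#' a known network with an implanted disease module: a network-local
#' set of genes that carries excess high-impact variants in cases only.
#'
#' Background variants arrive per gene per sample as
#' `Poisson(variant_rate)` with impact scores drawn from
#' `Beta(bg_shape)` (skewed low: most coding variants are mild). In
#' case samples, module genes have their variant rate multiplied by
#' `rate_multiplier` and impacts drawn from `case_vis_shape` (skewed
#' high). Zygosity is 1 plus a Bernoulli(`p_hom`) draw — homozygous
#' variants are rare. Setting `rate_multiplier = 1` and
#' `case_vis_shape = NULL` gives a null cohort in which cases and
#' controls are exchangeable.
#'
#' @param n_genes Number of network genes (default 400).
#' @param model Network model: `"scale-free"` (preferential attachment,
#'   default), `"stochastic-block"`, or `"small-world"`.
#' @param module_size Implanted module size (default 25).
#' @param n_case,n_ctrl Cohort sizes (default 300 each).
#' @param variant_rate Background variant rate per gene per sample
#'   (default 0.1).
#' @param bg_shape Beta shape pair for background impact scores
#'   (default `c(1, 4)`, mean 0.2).
#' @param rate_multiplier Case-only rate multiplier on module genes
#'   (default 3; 1 = null).
#' @param case_vis_shape Beta shape pair for module-gene impacts in
#'   cases (default `c(4, 2)`, mean 2/3); `NULL` keeps the background
#'   distribution (null on impact).
#' @param p_hom Probability that a variant is homozygous (default
#'   0.05).
#' @param seed RNG seed; every random draw in the simulator flows
#'   through it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 400, model = "scale-free",
                              module_size = 25, n_case = 300,
                              n_ctrl = 300, variant_rate = 0.1,
                              bg_shape = c(1, 4), rate_multiplier = 3,
                              case_vis_shape = c(4, 2), p_hom = 0.05,
                              seed = 1L) {
  stopifnot(module_size < n_genes, variant_rate >= 0,
            rate_multiplier >= 0, p_hom >= 0, p_hom <= 1,
            n_case >= 1, n_ctrl >= 1)
  model <- match.arg(model,
                     c("scale-free", "stochastic-block", "small-world"))
  structure(list(n_genes = n_genes, model = model,
                 module_size = module_size, n_case = n_case,
                 n_ctrl = n_ctrl, variant_rate = variant_rate,
                 bg_shape = bg_shape, rate_multiplier = rate_multiplier,
                 case_vis_shape = case_vis_shape, p_hom = p_hom,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate an interaction network with a ground-truth disease module
#'
#' Generates a random graph under the configured model (largest
#' connected component retained), labels genes `G0001...`, and selects
#' a network-local disease module: the highest-degree hub and its
#' nearest neighbors, extended outward by graph distance only if the
#' hub's neighborhood is too small. Module genes are therefore mutually
#' proximate (pairwise distance 2 or less through the hub whenever the
#' hub degree allows), matching the premise that disease signal is a
#' local network perturbation.
#'
#' @param config A [simulation_config()].
#' @return List with `network` (an `interaction_network`) and `module`
#'   (character vector of ground-truth module genes).
#' @export
simulate_network <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  g <- switch(config$model,
    "scale-free" = igraph::sample_pa(n, power = 1, m = 3,
                                     directed = FALSE),
    "small-world" = igraph::sample_smallworld(1, n, nei = 3, p = 0.05),
    "stochastic-block" = {
      k <- max(2L, round(n / 50))
      sizes <- rep(n %/% k, k)
      sizes[seq_len(n - sum(sizes))] <- sizes[seq_len(n - sum(sizes))] + 1L
      pm <- matrix(0.01, k, k); diag(pm) <- 0.15
      igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
    })
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership ==
                                           which.max(comp$csize)))
  nv <- igraph::vcount(g)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(nv))
  if (config$module_size > nv) {
    stop("module_size exceeds the largest connected component (",
         nv, " nodes)")
  }
  deg <- igraph::degree(g)
  hub <- which.max(deg)
  nbrs <- as.integer(igraph::neighbors(g, hub))
  nbrs <- nbrs[order(-deg[nbrs], nbrs)]
  module_idx <- c(hub, nbrs)
  if (length(module_idx) < config$module_size) {
    # hub neighborhood too small: extend by increasing graph distance
    dist <- as.integer(igraph::distances(g, v = hub))
    rest <- setdiff(order(dist, -deg, seq_len(nv)), module_idx)
    module_idx <- c(module_idx, rest)
  }
  module_idx <- module_idx[seq_len(config$module_size)]
  list(network = as_interaction_network(g),
       module = sort(igraph::V(g)$name[module_idx]))
}

#' Simulate a case-control variant cohort on a network
#'
#' Draws per-sample per-gene variant counts, impact scores and
#' zygosities under the generative model described in
#' [simulation_config()], implanting excess high-impact variants in
#' case samples on the ground-truth module genes. Output uses the
#' variant-table dialect consumed by [build_ps_matrix()] /
#' [write_variant_table()].
#'
#' @param network An `interaction_network` (from [simulate_network()]).
#' @param module Character vector of ground-truth module genes.
#' @param config A [simulation_config()].
#' @param seed Optional override of `config$seed` (so several cohorts
#'   can be drawn on one fixed network).
#' @return List with `records` (variant record frame), `phenotypes`
#'   (named status vector) and `module` (echoed truth).
#' @export
simulate_cohort <- function(network, module, config, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  genes <- network$genes
  n_g <- length(genes)
  samples <- c(sprintf("CASE%04d", seq_len(config$n_case)),
               sprintf("CTRL%04d", seq_len(config$n_ctrl)))
  status <- stats::setNames(rep(c("case", "control"),
                                c(config$n_case, config$n_ctrl)),
                            samples)
  is_module <- genes %in% module
  rate <- matrix(config$variant_rate, n_g, length(samples))
  rate[is_module, status == "case"] <-
    config$variant_rate * config$rate_multiplier
  k <- stats::rpois(length(rate), rate)
  if (sum(k) == 0L) {
    warning("simulated cohort contains no variants")
    rec <- data.frame(sample_id = character(0), gene = character(0),
                      vis = numeric(0), zygosity = integer(0),
                      inert = logical(0), stringsAsFactors = FALSE)
    return(list(records = rec, phenotypes = status, module = module))
  }
  gi <- rep(rep(seq_len(n_g), length(samples)), k)
  si <- rep(rep(seq_along(samples), each = n_g), k)
  shifted <- is_module[gi] & status[si] == "case" &
    !is.null(config$case_vis_shape)
  vis <- numeric(length(gi))
  vis[!shifted] <- stats::rbeta(sum(!shifted), config$bg_shape[1],
                                config$bg_shape[2])
  if (any(shifted)) {
    vis[shifted] <- stats::rbeta(sum(shifted), config$case_vis_shape[1],
                                 config$case_vis_shape[2])
  }
  rec <- data.frame(sample_id = samples[si],
                    gene = genes[gi],
                    vis = vis,
                    zygosity = 1L + stats::rbinom(length(gi), 1,
                                                  config$p_hom),
                    stringsAsFactors = FALSE)
  rec$inert <- FALSE
  list(records = rec, phenotypes = status, module = module)
}

#' Randomly perturb network edges
#'
#' Deletes and/or adds a fixed fraction of edges uniformly at random,
#' emulating false-negative and false-positive interactions. Deletion
#' can be restricted to edges touching a given gene set (the biased
#' deletion variant that targets identified genes). Added edges are
#' drawn uniformly from the absent pairs; the addition fraction is
#' measured relative to the unmodified edge count and may exceed 1.
#'
#' @param network An `interaction_network`.
#' @param delete_frac Fraction of existing edges to delete, in
#'   \[0, 1\].
#' @param add_frac Fraction of edges to add relative to the original
#'   edge count, in \[0, 1.1\].
#' @param restrict_to Optional character vector: deletion is restricted
#'   to edges incident to these genes.
#' @param seed Optional RNG seed.
#' @return The modified `interaction_network` (same gene set).
#' @export
perturb_edges <- function(network, delete_frac = 0, add_frac = 0,
                          restrict_to = NULL, seed = NULL) {
  stopifnot(delete_frac >= 0, delete_frac <= 1,
            add_frac >= 0, add_frac <= 1.1)
  if (!is.null(seed)) set.seed(seed)
  edges <- network$edges
  n_orig <- nrow(edges)
  if (delete_frac > 0) {
    pool <- seq_len(n_orig)
    if (!is.null(restrict_to)) {
      idx <- which(network$genes %in% toupper(restrict_to))
      pool <- which(edges[, 1] %in% idx | edges[, 2] %in% idx)
    }
    n_del <- min(length(pool), round(delete_frac * n_orig))
    if (n_del > 0) edges <- edges[-sample(pool, n_del), , drop = FALSE]
  }
  if (add_frac > 0) {
    n_add <- round(add_frac * n_orig)
    n <- length(network$genes)
    existing <- c((edges[, 1] - 1) * n + edges[, 2],
                  (network$edges[, 1] - 1) * n + network$edges[, 2])
    new_edges <- matrix(integer(0), 0, 2)
    while (nrow(new_edges) < n_add) {
      i <- sample.int(n, 2 * n_add, replace = TRUE)
      j <- sample.int(n, 2 * n_add, replace = TRUE)
      lo <- pmin(i, j); hi <- pmax(i, j)
      ok <- lo != hi & !((lo - 1) * n + hi) %in% existing
      cand <- unique(cbind(lo, hi)[ok, , drop = FALSE])
      new_edges <- unique(rbind(new_edges, cand))
    }
    new_edges <- new_edges[seq_len(n_add), , drop = FALSE]
    edges <- rbind(edges, new_edges)
  }
  interaction_network(network$genes, edges)
}

#' Precision, recall and ranking AUROC against a ground-truth module
#'
#' Evaluates a scored gene table against the known disease module:
#' precision and recall of the candidate set, recall within the
#' top-`|module|` genes ranked by absolute distance, and the AUROC of
#' the absolute-distance ranking for separating module from background
#' genes (computed exactly from the Mann-Whitney rank statistic, with
#' ties mid-ranked).
#'
#' @param scores A `gene_embed` fit or its `scores` data frame (columns
#'   `gene`, `distance`, and optionally `candidate`).
#' @param truth Character vector of ground-truth module genes.
#' @return List with `precision`, `recall`, `top_recall`, `auroc`, and
#'   `n_candidates`. Precision is `NA` when no gene is called.
#' @export
evaluate_recovery <- function(scores, truth) {
  if (inherits(scores, "gene_embed")) scores <- scores$scores
  stopifnot(length(truth) >= 1)
  truth <- unique(toupper(truth))
  gene <- toupper(scores$gene)
  pos <- gene %in% truth
  if (!any(pos)) stop("no overlap between scored genes and the truth set")
  score <- abs(scores$distance)
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(score)
  auroc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  top <- gene[order(-score)][seq_len(min(length(truth), nrow(scores)))]
  cand <- if (!is.null(scores$candidate)) gene[scores$candidate]
          else character(0)
  list(precision = if (length(cand)) mean(cand %in% truth) else NA_real_,
       recall = length(intersect(cand, truth)) / length(truth),
       top_recall = length(intersect(top, truth)) / length(truth),
       auroc = auroc,
       n_candidates = length(cand))
}
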