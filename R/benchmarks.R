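#' Robustness benchmark harness on synthetic cohorts
#'
#' Runs the robustness experiments the method is characterized by, all
#' on one simulated cohort with a known implanted disease module:
#' \describe{
#'   \item{downsampling}{refits on random sample subsets at fractions
#'     0.8, 0.6, 0.4, 0.2, 0.1 and 0.05 (per group) and measures
#'     precision/recall of each downsampled candidate set against the
#'     full-cohort candidate set, plus recovery of the true module.}
#'   \item{edge perturbation}{refits after deleting (or adding) random
#'     fractions of network edges — emulated false negative/positive
#'     interactions — and measures recovery of the true module.}
#'   \item{label shuffling}{refits with permuted phenotype labels and
#'     reports the Spearman correlation between the absolute-distance
#'     ranking and node degree, compared with the same correlation
#'     under true labels; with labels destroyed, ranking reflects
#'     network centrality rather than disease signal.}
#' }
#'
#' @param config A [simulation_config()] describing the cohort.
#' @param downsample_fracs Sample fractions for the downsampling sweep.
#' @param delete_fracs Edge-deletion fractions for the perturbation
#'   sweep.
#' @param add_fracs Edge-addition fractions (default none).
#' @param n_shuffles Number of label-shuffle replicates (default 3).
#' @param ... Further arguments passed to [gene_embed()].
#' @return List of class `perturbnet_benchmarks` with data frames
#'   `downsampling`, `edge_perturbation`, `label_shuffle`, and the
#'   reference fit's recovery metrics under `reference`.
#' @export
run_benchmarks <- function(config = simulation_config(),
                           downsample_fracs = c(0.8, 0.6, 0.4, 0.2,
                                                0.1, 0.05),
                           delete_fracs = c(0.2, 0.4),
                           add_fracs = numeric(0),
                           n_shuffles = 3, ...) {
  net <- simulate_network(config)
  coh <- simulate_cohort(net$network, net$module, config)
  fit0 <- gene_embed(coh$records, coh$phenotypes, net$network,
                     seed = config$seed, ...)
  ref_cand <- candidates(fit0)
  ref_eval <- evaluate_recovery(fit0, net$module)

  subset_cohort <- function(samples) {
    list(records = coh$records[coh$records$sample_id %in% samples, ,
                               drop = FALSE],
         phenotypes = coh$phenotypes[samples])
  }
  down <- lapply(downsample_fracs, function(f) {
    cases <- names(coh$phenotypes)[coh$phenotypes == "case"]
    ctrls <- names(coh$phenotypes)[coh$phenotypes == "control"]
    keep <- c(sample(cases, max(2, round(f * length(cases)))),
              sample(ctrls, max(4, round(f * length(ctrls)))))
    sub <- subset_cohort(keep)
    fit <- gene_embed(sub$records, sub$phenotypes, net$network,
                      seed = config$seed, ...)
    cand <- candidates(fit)
    ev <- evaluate_recovery(fit, net$module)
    data.frame(fraction = f,
               n_candidates = length(cand),
               precision_vs_full = if (length(cand))
                 mean(cand %in% ref_cand) else NA_real_,
               recall_vs_full = if (length(ref_cand))
                 length(intersect(cand, ref_cand)) / length(ref_cand)
               else NA_real_,
               auroc_truth = ev$auroc,
               top_recall_truth = ev$top_recall)
  })
  edge_rows <- list()
  for (f in delete_fracs) {
    pnet <- perturb_edges(net$network, delete_frac = f,
                          seed = config$seed + round(1000 * f))
    fit <- gene_embed(coh$records, coh$phenotypes, pnet,
                      seed = config$seed, ...)
    ev <- evaluate_recovery(fit, net$module)
    edge_rows[[length(edge_rows) + 1L]] <-
      data.frame(kind = "delete", fraction = f, auroc = ev$auroc,
                 top_recall = ev$top_recall,
                 n_candidates = ev$n_candidates)
  }
  for (f in add_fracs) {
    pnet <- perturb_edges(net$network, add_frac = f,
                          seed = config$seed + round(2000 * f))
    fit <- gene_embed(coh$records, coh$phenotypes, pnet,
                      seed = config$seed, ...)
    ev <- evaluate_recovery(fit, net$module)
    edge_rows[[length(edge_rows) + 1L]] <-
      data.frame(kind = "add", fraction = f, auroc = ev$auroc,
                 top_recall = ev$top_recall,
                 n_candidates = ev$n_candidates)
  }
  edge_tab <- rbind(
    data.frame(kind = "delete", fraction = 0, auroc = ref_eval$auroc,
               top_recall = ref_eval$top_recall,
               n_candidates = ref_eval$n_candidates),
    do.call(rbind, edge_rows))

  deg <- stats::setNames(igraph::degree(as_igraph(net$network)),
                         net$network$genes)
  rank_degree_cor <- function(fit) {
    sc <- fit$scores
    stats::cor(abs(sc$distance), deg[sc$gene], method = "spearman")
  }
  shuf <- lapply(seq_len(n_shuffles), function(i) {
    set.seed(config$seed + 100 + i)
    perm <- stats::setNames(sample(coh$phenotypes),
                            names(coh$phenotypes))
    fit <- gene_embed(coh$records, perm, net$network,
                      seed = config$seed + 100 + i, ...)
    data.frame(replicate = i,
               degree_cor_shuffled = rank_degree_cor(fit),
               n_candidates = fit$log$n_candidates)
  })
  shuffle_tab <- do.call(rbind, shuf)
  shuffle_tab$degree_cor_true <- rank_degree_cor(fit0)

  structure(list(reference = ref_eval,
                 downsampling = do.call(rbind, down),
                 edge_perturbation = edge_tab,
                 label_shuffle = shuffle_tab,
                 config = config),
            class = "perturbnet_benchmarks")
}

#' @export
print.perturbnet_benchmarks <- function(x, ...) {
  cat("Synthetic robustness benchmarks (", x$config$n_genes, " genes, ",
      x$config$n_case, "+", x$config$n_ctrl, " samples, module ",
      x$config$module_size, ")\n\n", sep = "")
  cat("Reference recovery: AUROC ", round(x$reference$auroc, 3),
      ", top-module recall ", round(x$reference$top_recall, 3), "\n\n",
      sep = "")
  cat("Downsampling:\n")
  print(x$downsampling, row.names = FALSE, digits = 3)
  cat("\nEdge perturbation:\n")
  print(x$edge_perturbation, row.names = FALSE, digits = 3)
  cat("\nLabel shuffling (|distance| vs degree, Spearman):\n")
  print(x$label_shuffle, row.names = FALSE, digits = 3)
  invisible(x)
}
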