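#' Fit the case-control network perturbation model
#'
#' Runs the full gene-prioritization pipeline: per-sample gene
#' perturbation scores are aggregated from annotated coding variants,
#' mapped onto a protein-interaction network as edge weights, averaged
#' into a case and a control cohort graph, and both graphs are embedded
#' with heat-kernel spectral graph wavelets summarized by empirical
#' characteristic functions. Per-gene distances between the paired
#' embeddings (projected on the first principal component by default)
#' are standardized to z-scores, tested one-tailed, corrected with
#' Benjamini-Hochberg, and thresholded at `q < alpha` to give
#' pre-candidate genes. A control-versus-control rerun on a random
#' split of the controls removes genes whose perturbation differences
#' reflect background variation; the survivors are the candidate genes.
#'
#' Both cohort graphs share the network topology, and the control graph
#' is embedded with the wavelet scales selected on the case graph, so
#' the two feature spaces are directly comparable. Disconnected
#' networks are analyzed per connected component of at least
#' `min_component` nodes; smaller components are excluded and recorded.
#'
#' @param variants Variant record frame (see [read_variant_table()]) or
#'   a path to a variant TSV.
#' @param phenotypes Named status vector (`"case"`/`"control"`) or a
#'   path to a phenotype TSV.
#' @param network An `interaction_network` or a path to an edge-list
#'   TSV.
#' @param vis_column Impact column name when `variants` is a path.
#' @param weighting Edge weighting scheme: `"sum"` (default), `"max"`,
#'   or `"threshold"`.
#' @param tau Dead-edge threshold for the `threshold` scheme.
#' @param distance Distance mode: `"pca"` (default) or `"full"`.
#' @param alpha FDR threshold (default 0.01).
#' @param tail Tail of the one-tailed Z-test: `"upper"` (default),
#'   `"lower"`, or `"both"`.
#' @param embedding An [embedding_config()].
#' @param qc Apply site-level QC ([apply_qc_filters()]) first? Only
#'   possible when records carry a `variant_id` column; default `FALSE`.
#' @param hwe_threshold,rate_threshold QC thresholds (defaults `5e-8`
#'   and `0.95`).
#' @param cc_filter Run the control-versus-control false-positive
#'   filter (default `TRUE`)?
#' @param min_component Minimum connected-component size (default 3).
#' @param seed RNG seed governing the control-split (and any other
#'   randomness); recorded in the fit.
#' @return An object of class `gene_embed`: a list with
#'   \describe{
#'     \item{scores}{data frame `gene, distance, z, p, q,
#'       precandidate, candidate`, sorted by decreasing `z`.}
#'     \item{fp_genes}{genes removed by the control-vs-control filter.}
#'     \item{var_explained}{fraction of variance captured by PC1
#'       (`NA` in full-distance mode).}
#'     \item{config}{all effective parameters, including the seed.}
#'     \item{log}{per-stage counts (records read, genes matched,
#'       components embedded, candidates).}
#'   }
#' @seealso [evaluate_recovery()], [simulate_cohort()],
#'   [run_benchmarks()]
#' @examples
#' cfg <- simulation_config(n_genes = 120, module_size = 10,
#'                          n_case = 40, n_ctrl = 40, seed = 7)
#' net <- simulate_network(cfg)
#' coh <- simulate_cohort(net$network, net$module, cfg)
#' fit <- gene_embed(coh$records, coh$phenotypes, net$network, seed = 7)
#' head(summary(fit))
#' @export
gene_embed <- function(variants, phenotypes, network,
                       vis_column = "vis",
                       weighting = c("sum", "max", "threshold"),
                       tau = 0.7,
                       distance = c("pca", "full"),
                       alpha = 0.01,
                       tail = c("upper", "lower", "both"),
                       embedding = embedding_config(),
                       qc = FALSE,
                       hwe_threshold = 5e-8, rate_threshold = 0.95,
                       cc_filter = TRUE,
                       min_component = 3,
                       seed = 1L) {
  weighting <- match.arg(weighting)
  distance <- match.arg(distance)
  tail <- match.arg(tail)
  stopifnot(alpha > 0, alpha < 1)
  cl <- match.call()
  set.seed(seed)

  if (is.character(variants)) {
    variants <- read_variant_table(variants, vis_column = vis_column)
  }
  if (is.character(phenotypes) && length(phenotypes) == 1L &&
      is.null(names(phenotypes))) {
    phenotypes <- read_phenotypes(phenotypes)
  }
  if (is.character(network)) network <- read_edge_list(network)
  if (!inherits(network, "interaction_network")) {
    stop("'network' must be an interaction_network or an edge-list path")
  }
  if (!any(phenotypes == "case") || !any(phenotypes == "control")) {
    stop("phenotypes must include at least one case and one control")
  }
  log <- list(n_records = nrow(variants),
              n_samples = length(phenotypes))
  if (qc) {
    variants <- apply_qc_filters(variants, phenotypes,
                                 hwe_threshold = hwe_threshold,
                                 rate_threshold = rate_threshold)
    log$qc <- attr(variants, "qc_report")
    log$n_records_post_qc <- nrow(variants)
  }

  ps <- build_ps_matrix(variants, phenotypes, network$genes)
  log$n_genes_dropped_off_network <- attr(ps, "n_dropped_genes")
  graphs <- build_cohort_graphs(ps, phenotypes, network,
                                scheme = weighting, tau = tau)
  emb <- embed_cohort_pair(graphs$case, graphs$control, embedding,
                           min_component = min_component)
  log$n_genes_embedded <- nrow(emb$case)
  log$n_genes_excluded_small_components <- length(emb$excluded_genes)
  scores <- rank_from_embeddings(emb, distance_mode = distance,
                                 alpha = alpha, tail = tail)
  var_explained <- attr(scores, "var_explained")
  log$n_precandidates <- sum(scores$precandidate)

  fp <- character(0)
  if (cc_filter) {
    fp <- control_control_filter(ps, phenotypes, network,
                                 scheme = weighting, tau = tau,
                                 config = embedding,
                                 distance_mode = distance,
                                 alpha = alpha, tail = tail,
                                 min_component = min_component)
  }
  scores$candidate <- scores$precandidate & !scores$gene %in% fp
  log$n_candidates <- sum(scores$candidate)
  scores <- scores[order(-replace(scores$z, is.na(scores$z), -Inf),
                         scores$gene), ]
  rownames(scores) <- NULL

  structure(list(scores = scores,
                 fp_genes = as.character(fp),
                 var_explained = var_explained,
                 scales = emb$scales,
                 excluded_genes = emb$excluded_genes,
                 config = list(weighting = weighting, tau = tau,
                               distance = distance, alpha = alpha,
                               tail = tail, embedding = embedding,
                               qc = qc, hwe_threshold = hwe_threshold,
                               rate_threshold = rate_threshold,
                               cc_filter = cc_filter,
                               min_component = min_component,
                               seed = seed),
                 log = log,
                 call = cl),
            class = "gene_embed")
}

#' @export
print.gene_embed <- function(x, ...) {
  cat("Case-control network perturbation fit\n")
  cat("  genes embedded:  ", x$log$n_genes_embedded, "\n")
  cat("  samples:         ", x$log$n_samples, "\n")
  if (!is.null(x$var_explained) && is.finite(x$var_explained)) {
    cat("  PC1 variance explained: ",
        sprintf("%.1f%%", 100 * x$var_explained), "\n")
  }
  cat("  pre-candidates (q < ", x$config$alpha, "): ",
      x$log$n_precandidates, "\n", sep = "")
  cat("  candidates:      ", x$log$n_candidates, "\n")
  if (x$log$n_candidates > 0) {
    cat("  top candidates:  ",
        paste(utils::head(x$scores$gene[x$scores$candidate], 10),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summarize a gene_embed fit
#'
#' @param object A `gene_embed` fit.
#' @param n Number of top-ranked genes to return (default all).
#' @param ... Unused.
#' @return The score data frame (gene, distance, z, p, q,
#'   precandidate, candidate), ordered by decreasing z.
#' @export
summary.gene_embed <- function(object, n = Inf, ...) {
  utils::head(object$scores, n)
}

#' Signed gene distances from a fit
#' @param object A `gene_embed` fit.
#' @param ... Unused.
#' @return Named numeric vector of signed embedding distances.
#' @export
coef.gene_embed <- function(object, ...) {
  stats::setNames(object$scores$distance, object$scores$gene)
}

#' Candidate genes from a fit
#' @param fit A `gene_embed` fit.
#' @param precandidates Return pre-candidates (before the
#'   control-vs-control filter) instead? Default `FALSE`.
#' @return Character vector of gene symbols.
#' @export
candidates <- function(fit, precandidates = FALSE) {
  stopifnot(inherits(fit, "gene_embed"))
  flag <- if (precandidates) fit$scores$precandidate
          else fit$scores$candidate
  fit$scores$gene[flag]
}

#' Plot the signed distance distribution of a fit
#'
#' Histogram of the per-gene signed distances with the z-score
#' candidate threshold region marked and candidate genes shown in the
#' rug.
#'
#' @param x A `gene_embed` fit.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.gene_embed <- function(x, ...) {
  d <- x$scores$distance
  graphics::hist(d, breaks = 50, col = "grey85", border = "white",
                 main = "Signed embedding distances",
                 xlab = "signed distance (case - control, PC1)", ...)
  cand <- x$scores$distance[x$scores$candidate]
  if (length(cand)) {
    graphics::rug(cand, col = "firebrick", lwd = 2)
    graphics::legend("topright", legend = "candidate genes",
                     col = "firebrick", lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Write the score table and run manifest of a fit
#'
#' Writes `scores.tsv` (the full gene score table),
#' `candidates.txt` (one candidate symbol per line) and
#' `manifest.json` (every effective parameter, the seed, per-stage
#' counts and PC1 variance explained) into `dir`. Numeric formatting
#' is fixed so that identical fits produce byte-identical files.
#'
#' @param fit A `gene_embed` fit.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_gene_embed <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- fit$scores
  for (col in c("distance", "z", "p", "q")) {
    sc[[col]] <- sprintf("%.10g", sc[[col]])
  }
  utils::write.table(sc, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(candidates(fit), file.path(dir, "candidates.txt"))
  manifest <- c(fit$config[setdiff(names(fit$config), "embedding")],
                fit$config$embedding[c("J", "d", "t_max", "eta")],
                list(var_explained = fit$var_explained,
                     fp_genes = fit$fp_genes),
                fit$log[c("n_records", "n_samples", "n_genes_embedded",
                          "n_precandidates", "n_candidates")])
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
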