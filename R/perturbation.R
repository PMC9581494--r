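#' Gene-level perturbation score
#'
#' Collapses the variants observed in one gene of one sample into a
#' single perturbation score
#' \deqn{PS = 1 - \prod_i (1 - VIS_i)^{zyg_i}}
#' the probability that at least one variant allele disrupts the gene
#' product, treating per-allele impact scores as independent damage
#' probabilities. The score is order-independent, monotone in added
#' variants, and saturates at 1 as soon as any variant has VIS = 1.
#'
#' The product is accumulated in `log1p` space so that many small-impact
#' variants cannot underflow; an exact zero factor (VIS = 1 with
#' zygosity > 0) short-circuits to PS = 1.
#'
#' @param vis Numeric vector of variant impact scores in \[0, 1\].
#' @param zygosity Integer vector in \{0, 1, 2\}, recycled against `vis`.
#' @return The perturbation score, a scalar in \[0, 1\]. No variants
#'   (empty input) gives 0.
#' @examples
#' perturbation_score(numeric(0), integer(0))  # 0
#' perturbation_score(0.5, 2)                  # 0.75
#' perturbation_score(c(0.2, 0.5), c(1, 1))    # 0.6
#' @export
perturbation_score <- function(vis, zygosity) {
  if (length(vis) == 0L) return(0)
  stopifnot(length(zygosity) == length(vis))
  if (any(!is.finite(vis) | vis < 0 | vis > 1)) {
    stop("variant impact scores must lie in [0, 1]")
  }
  if (any(!zygosity %in% 0:2)) stop("zygosity must be in {0, 1, 2}")
  live <- zygosity > 0L
  if (!any(live)) return(0)
  v <- vis[live]
  z <- zygosity[live]
  if (any(v >= 1)) return(1)
  -expm1(sum(z * log1p(-v)))
}

#' Build the gene-by-sample perturbation matrix
#'
#' Computes [perturbation_score()] for every (gene, sample) cell over
#' all samples in the phenotype table, restricted to genes present in
#' the interaction network. Cells with no qualifying variants score 0.
#' Records for genes outside the network are dropped and counted.
#'
#' @param records Variant record frame (see [read_variant_table()]).
#' @param phenotypes Named status vector; defines the sample set and
#'   column order.
#' @param network_genes Character vector of network gene symbols.
#' @return Numeric matrix (genes x samples) with `dimnames`, values in
#'   \[0, 1\]. Attribute `n_dropped_genes` counts record genes absent
#'   from the network.
#' @export
build_ps_matrix <- function(records, phenotypes, network_genes) {
  if (length(network_genes) == 0L) stop("network gene set is empty")
  genes <- unique(toupper(network_genes))
  samples <- names(phenotypes)
  ps <- matrix(0, length(genes), length(samples),
               dimnames = list(genes, samples))
  n_dropped <- length(setdiff(unique(records$gene), genes))
  rec <- records[records$zygosity > 0L, , drop = FALSE]
  if (nrow(rec) > 0L) {
    in_net <- rec$gene %in% genes
    if (!any(in_net)) {
      stop("no overlap between variant genes and network genes: ",
           "nothing to analyze")
    }
    rec <- rec[in_net & rec$sample_id %in% samples, , drop = FALSE]
    # PS = 1 - exp(sum zyg*log1p(-vis)); -Inf from vis = 1 yields PS = 1
    gi <- match(rec$gene, genes)
    si <- match(rec$sample_id, samples)
    cell <- (si - 1L) * length(genes) + gi
    logterm <- rec$zygosity * log1p(-pmin(rec$vis, 1))
    agg <- rowsum(logterm, group = cell)
    ps[as.integer(rownames(agg))] <- -expm1(agg[, 1])
  }
  attr(ps, "n_dropped_genes") <- n_dropped
  ps
}

#' Export a perturbation matrix as TSV
#' @param ps Matrix from [build_ps_matrix()].
#' @param path Output path (genes in rows, samples in columns).
#' @return `path`, invisibly.
#' @export
write_ps_matrix <- function(ps, path) {
  utils::write.table(data.frame(gene = rownames(ps), ps,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
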