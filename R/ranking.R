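#' First-principal-component projections of paired embeddings
#'
#' Stacks the case and control embedding matrices (2N rows), mean-centers
#' the columns, and projects every row onto the first principal axis of
#' the stacked matrix. Fitting PCA jointly on both cohorts puts the two
#' projections on a shared basis; the first component serves to denoise
#' the full-dimensional embeddings. The axis sign is fixed so that the
#' loading with the largest absolute value is positive, making the
#' signed distances deterministic.
#'
#' @param case_embedding,control_embedding Node x feature matrices with
#'   identical row order and feature count.
#' @return List with `case` and `control` projection vectors (named by
#'   gene when the embeddings carry row names) and `var_explained`, the
#'   fraction of total variance captured by the first component (`NA`
#'   when the stacked matrix has no variance, in which case all
#'   projections are 0).
#' @export
pc1_scores <- function(case_embedding, control_embedding) {
  stopifnot(nrow(case_embedding) == nrow(control_embedding),
            ncol(case_embedding) == ncol(control_embedding))
  n <- nrow(case_embedding)
  X <- rbind(case_embedding, control_embedding)
  X <- sweep(X, 2, colMeans(X))
  total_var <- sum(X^2)
  genes <- rownames(case_embedding)
  if (total_var < 1e-12) {
    zero <- stats::setNames(rep(0, n), genes)
    return(list(case = zero, control = zero, var_explained = NA_real_))
  }
  sv <- svd(X, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  proj <- drop(X %*% v)
  list(case = stats::setNames(proj[seq_len(n)], genes),
       control = stats::setNames(proj[n + seq_len(n)], genes),
       var_explained = sv$d[1]^2 / total_var)
}

#' Signed square-root distances between paired projections
#'
#' Per-gene distance between its case and control positions on the
#' first principal axis:
#' \deqn{d_g = \mathrm{sign}(p^{case}_g - p^{ctrl}_g)
#'       \sqrt{|p^{case}_g - p^{ctrl}_g|}}
#' The square root compresses heavy tails so the signed distances form
#' an approximately gaussian distribution that the z-test downstream
#' assumes.
#'
#' @param projections List with `case` and `control` projection vectors
#'   (as from [pc1_scores()]).
#' @return Named numeric vector of signed distances.
#' @export
signed_distances <- function(projections) {
  delta <- projections$case - projections$control
  sign(delta) * sqrt(abs(delta))
}

#' Full-dimensional embedding distances
#'
#' Alternative distance mode: the square root of the euclidean norm of
#' the per-gene embedding difference,
#' `d_g = sqrt(||x_case,g - x_ctrl,g||_2)`. Always non-negative; the
#' z/FDR stage is then applied to this distribution. The PCA mode is
#' the default because the first component denoises graph-wide weight
#' fluctuations that contaminate the full embedding.
#'
#' @param case_embedding,control_embedding Node x feature matrices with
#'   identical shape and row order.
#' @return Named numeric vector of non-negative distances.
#' @export
full_embedding_distances <- function(case_embedding, control_embedding) {
  stopifnot(dim(case_embedding) == dim(control_embedding))
  d2 <- rowSums((case_embedding - control_embedding)^2)
  stats::setNames(sqrt(sqrt(d2)), rownames(case_embedding))
}

#' z-scores, one-tailed p-values and FDR flags for gene distances
#'
#' Standardizes the gene distance distribution (population standard
#' deviation, for determinism), computes one-tailed Z-test p-values
#' (upper tail by default), applies Benjamini-Hochberg FDR correction,
#' and flags pre-candidate genes at `q < alpha`.
#'
#' @param distances Named numeric vector of per-gene distances.
#' @param alpha FDR threshold for pre-candidates (default 0.01).
#' @param tail `"upper"` (default), `"lower"`, or `"both"`.
#' @return A `data.frame` with columns `gene`, `distance`, `z`, `p`,
#'   `q`, `precandidate`. If the distance distribution is degenerate
#'   (zero standard deviation), `z`, `p`, `q` are `NA`, no gene is
#'   flagged, and a warning is raised.
#' @export
z_fdr <- function(distances, alpha = 0.01,
                  tail = c("upper", "lower", "both")) {
  tail <- match.arg(tail)
  stopifnot(length(distances) >= 2, alpha > 0, alpha < 1)
  mu <- mean(distances)
  sd_pop <- sqrt(mean((distances - mu)^2))
  out <- data.frame(gene = names(distances), distance = unname(distances),
                    stringsAsFactors = FALSE)
  if (!is.finite(sd_pop) || sd_pop < 1e-300) {
    warning("distance distribution is degenerate (zero spread): ",
            "no candidates can be called")
    out$z <- NA_real_
    out$p <- NA_real_
    out$q <- NA_real_
    out$precandidate <- FALSE
    return(out)
  }
  z <- (distances - mu) / sd_pop
  p <- switch(tail,
              upper = stats::pnorm(z, lower.tail = FALSE),
              lower = stats::pnorm(z),
              both = 2 * stats::pnorm(-abs(z)))
  out$z <- unname(z)
  out$p <- unname(p)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$precandidate <- out$q < alpha
  out
}

# Distances + score table for one embedded case/control pair.
rank_from_embeddings <- function(emb_pair, distance_mode = "pca",
                                 alpha = 0.01, tail = "upper") {
  if (distance_mode == "pca") {
    proj <- pc1_scores(emb_pair$case, emb_pair$control)
    d <- signed_distances(proj)
    ve <- proj$var_explained
  } else if (distance_mode == "full") {
    d <- full_embedding_distances(emb_pair$case, emb_pair$control)
    ve <- NA_real_
  } else {
    stop("unknown distance mode: ", distance_mode)
  }
  tab <- z_fdr(d, alpha = alpha, tail = tail)
  attr(tab, "var_explained") <- ve
  tab
}

#' Control-versus-control false-positive filter
#'
#' Reruns the full scoring pipeline on the control samples alone, split
#' uniformly at random into two pseudo-cohorts. Genes reaching
#' `q < alpha` in this healthy-versus-healthy comparison reflect
#' background (non-disease) variation; the set is returned for removal
#' from the pre-candidate list. With fewer than 4 control samples the
#' filter is skipped with a warning and an empty set is returned.
#'
#' @param ps Perturbation matrix (genes x samples) in network gene
#'   order.
#' @param phenotypes Named status vector.
#' @param network The `interaction_network` used for the main run.
#' @param scheme,tau Edge-weighting scheme and dead-edge threshold.
#' @param config [embedding_config()].
#' @param distance_mode,alpha,tail Passed through to the ranking stage.
#' @param min_component Minimum component size.
#' @return Character vector of false-positive gene symbols, with
#'   attribute `split` recording the pseudo-group assignment.
#' @export
control_control_filter <- function(ps, phenotypes, network,
                                   scheme = "sum", tau = 0.7,
                                   config = embedding_config(),
                                   distance_mode = "pca", alpha = 0.01,
                                   tail = "upper", min_component = 3) {
  ctrls <- names(phenotypes)[phenotypes == "control"]
  if (length(ctrls) < 4L) {
    warning("fewer than 4 control samples: control-vs-control filter ",
            "SKIPPED; candidate list equals the pre-candidate list")
    out <- character(0)
    attr(out, "split") <- NULL
    return(out)
  }
  half <- sample(ctrls, floor(length(ctrls) / 2))
  pseudo <- stats::setNames(ifelse(ctrls %in% half, "case", "control"),
                            ctrls)
  graphs <- build_cohort_graphs(ps[, ctrls, drop = FALSE], pseudo,
                                network, scheme = scheme, tau = tau)
  emb <- embed_cohort_pair(graphs$case, graphs$control, config,
                           min_component = min_component)
  tab <- suppressWarnings(
    rank_from_embeddings(emb, distance_mode, alpha, tail))
  fp <- tab$gene[tab$precandidate]
  attr(fp, "split") <- pseudo
  fp
}
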