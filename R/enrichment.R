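#' One-tailed hypergeometric overlap test
#'
#' Tests whether the overlap between a candidate gene set and a
#' reference gene set is larger than expected when candidates are drawn
#' uniformly from an explicit background universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N = |universe|,
#' K = |reference|, n = |candidates|)`. Genes outside the universe are
#' clipped from both sets (with a warning) before testing — the
#' universe is always explicit, never implied.
#'
#' @param candidates,reference Character vectors of gene symbols.
#' @param universe Character vector: the background gene set.
#' @return List with `overlap` (k), `p` (one-tailed upper p-value),
#'   and the clipped set sizes `n_candidates`, `n_reference`,
#'   `n_universe`.
#' @examples
#' u <- paste0("G", 1:10)
#' hypergeometric_overlap(u[1:4], u[c(1, 2, 7)], u)
#' @export
hypergeometric_overlap <- function(candidates, reference, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  candidates <- unique(candidates)
  reference <- unique(reference)
  n_clip <- sum(!candidates %in% universe) + sum(!reference %in% universe)
  if (n_clip > 0) {
    warning(n_clip, " gene(s) outside the universe clipped from the ",
            "tested sets")
    candidates <- intersect(candidates, universe)
    reference <- intersect(reference, universe)
  }
  k <- length(intersect(candidates, reference))
  # P(X >= k) = P(X > k - 1)
  p <- stats::phyper(k - 1, length(reference),
                     length(universe) - length(reference),
                     length(candidates), lower.tail = FALSE)
  list(overlap = k, p = min(1, p),
       n_candidates = length(candidates),
       n_reference = length(reference),
       n_universe = length(universe))
}

#' Permutation Z-test for the number of enriched categories
#'
#' Counts how many category gene sets are enriched in the candidate set
#' (one-tailed hypergeometric `p < p_enrich`), then compares that count
#' with its permutation null: `n_perm` random gene sets of the same
#' size as the candidates drawn uniformly from the universe, each
#' scored the same way. Returns the permutation z-score of the observed
#' count and its upper-tail normal p-value.
#'
#' @param candidates Character vector of candidate genes.
#' @param category_sets Named list of character vectors (e.g. gene sets
#'   for brain regions or pathways).
#' @param universe Background gene set.
#' @param n_perm Number of permutations (default 1000).
#' @param p_enrich Per-category enrichment threshold (default 0.05).
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `observed` (count of enriched categories), `z`,
#'   `p`, and `perm_mean`, `perm_sd` of the null counts.
#' @export
permutation_category_enrichment <- function(candidates, category_sets,
                                            universe, n_perm = 1000,
                                            p_enrich = 0.05,
                                            seed = NULL) {
  stopifnot(n_perm >= 100)
  universe <- unique(universe)
  if (length(unique(candidates)) > length(universe)) {
    stop("candidate set larger than the universe")
  }
  candidates <- intersect(unique(candidates), universe)
  if (!is.null(seed)) set.seed(seed)
  count_enriched <- function(gene_set) {
    sum(vapply(category_sets, function(cat) {
      suppressWarnings(
        hypergeometric_overlap(gene_set, cat, universe)$p) < p_enrich
    }, logical(1)))
  }
  observed <- count_enriched(candidates)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    count_enriched(sample(universe, length(candidates)))
  }, numeric(1))
  mu <- mean(null_counts)
  sdv <- stats::sd(null_counts)
  z <- if (sdv > 0) (observed - mu) / sdv else
    ifelse(observed > mu, Inf, ifelse(observed < mu, -Inf, 0))
  list(observed = observed, z = z,
       p = stats::pnorm(z, lower.tail = FALSE),
       perm_mean = mu, perm_sd = sdv)
}

#' Read gene sets from a plain list or GMT file
#'
#' Plain files hold one gene symbol per line and yield a single set
#' named after the file. GMT files (detected by extension or by rows
#' with 3+ tab-separated fields) hold one set per line:
#' name, description, members...
#'
#' @param path Path to the gene-set file.
#' @return Named list of character vectors (uppercased symbols).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("gene set file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_gmt <- grepl("\\.gmt$", path, ignore.case = TRUE) ||
    all(lengths(fields) >= 3)
  if (is_gmt) {
    sets <- lapply(fields, function(f) toupper(f[-(1:2)]))
    names(sets) <- vapply(fields, `[`, character(1), 1)
    sets
  } else {
    out <- list(toupper(trimws(lines)))
    names(out) <- sub("\\.[^.]*$", "", basename(path))
    out
  }
}
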