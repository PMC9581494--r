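#' Read a per-sample annotated variant table
#'
#' Reads a tab-separated table of per-sample coding variants, one row per
#' (sample, variant) observation, into a validated variant record frame.
#' Each record carries a gene symbol, a variant impact score (VIS) in
#' \[0, 1\] — e.g. an Evolutionary Action or PolyPhen2 probability of
#' functional damage — and a zygosity in \{0, 1, 2\} (0 wild type,
#' 1 heterozygous, 2 homozygous). Rows with zygosity 0 are retained but
#' marked inert: they encode explicit homozygous-reference calls, which
#' site-level QC needs to distinguish missing genotypes from wild type,
#' and they contribute nothing to downstream scoring.
#'
#' @param path Path to a tab-separated file with a header line. Required
#'   columns: `sample_id` (or `sample`), `gene`, `zygosity`, and the
#'   impact column named by `vis_column`. An optional `variant_id` column
#'   identifies the genomic site (needed for [apply_qc_filters()]).
#' @param vis_column Name of the impact-score column to use (e.g. `"ea"`
#'   or `"pph2"`, default `"vis"`).
#' @return A `data.frame` of validated variant records with columns
#'   `sample_id`, `gene`, `vis`, `zygosity`, `inert` (logical,
#'   `zygosity == 0`) and, when present in the input, `variant_id`.
#' @seealso [vcf_to_variant_table()], [apply_qc_filters()],
#'   [build_ps_matrix()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tgene\tzygosity\tea",
#'              "S1\tAPOE\t1\t0.8",
#'              "S2\tTREM2\t2\t0.35"), tf)
#' read_variant_table(tf, vis_column = "ea")
#' @export
read_variant_table <- function(path, vis_column = "vis") {
  if (!file.exists(path)) stop("variant table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(tab)
  if ("sample" %in% nm && !("sample_id" %in% nm)) {
    names(tab)[nm == "sample"] <- "sample_id"
    nm <- names(tab)
  }
  for (col in c("sample_id", "gene", "zygosity", vis_column)) {
    if (!col %in% nm) {
      stop("variant table is missing required column '", col, "'")
    }
  }
  rec <- data.frame(sample_id = as.character(tab$sample_id),
                    gene = toupper(as.character(tab$gene)),
                    vis = as.numeric(tab[[vis_column]]),
                    zygosity = suppressWarnings(as.integer(tab$zygosity)),
                    stringsAsFactors = FALSE)
  if ("variant_id" %in% nm) rec$variant_id <- as.character(tab$variant_id)
  if (nrow(rec) == 0L) {
    warning("variant table '", path, "' contains no records")
    rec$inert <- logical(0)
    return(rec)
  }
  bad_vis <- which(!is.finite(rec$vis) | rec$vis < 0 | rec$vis > 1)
  if (length(bad_vis)) {
    stop("variant impact score outside [0, 1] at row ", bad_vis[1],
         " (value: ", tab[[vis_column]][bad_vis[1]], ")")
  }
  bad_zyg <- which(is.na(rec$zygosity) | !rec$zygosity %in% 0:2)
  if (length(bad_zyg)) {
    stop("zygosity outside {0, 1, 2} at row ", bad_zyg[1],
         " (value: ", tab$zygosity[bad_zyg[1]], ")")
  }
  rec$inert <- rec$zygosity == 0L
  rec
}

#' Write a variant record frame to TSV
#'
#' Inverse of [read_variant_table()]; the impact column is written under
#' the name given by `vis_column` so the file round-trips.
#'
#' @param records Variant record frame.
#' @param path Output path.
#' @param vis_column Column name used for the impact score in the file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path, vis_column = "vis") {
  out <- data.frame(sample_id = records$sample_id,
                    gene = records$gene,
                    zygosity = records$zygosity,
                    stringsAsFactors = FALSE)
  out[[vis_column]] <- records$vis
  if (!is.null(records$variant_id)) out$variant_id <- records$variant_id
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path Tab-separated file with header columns `sample_id` and
#'   `status`, where status is `0`/`1` or `control`/`case`.
#' @return Named character vector mapping sample_id to `"case"` or
#'   `"control"`.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(tab))) {
    stop("phenotype file must have columns 'sample_id' and 'status'")
  }
  st <- tolower(as.character(tab$status))
  status <- ifelse(st %in% c("1", "case"), "case",
                   ifelse(st %in% c("0", "control"), "control", NA))
  if (anyNA(status)) {
    stop("phenotype status must be 0/1 or case/control; offending value: ",
         tab$status[which(is.na(status))[1]])
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicated sample_id in phenotype file: ",
         tab$sample_id[anyDuplicated(tab$sample_id)])
  }
  stats::setNames(status, as.character(tab$sample_id))
}

#' Write a phenotype table
#' @param phenotypes Named vector (sample -> "case"/"control").
#' @param path Output path; status written as 1/0.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(
    data.frame(sample_id = names(phenotypes),
               status = as.integer(phenotypes == "case")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a VCF plus impact-annotation map to a variant record frame
#'
#' Decodes per-sample genotypes from a VCF 4.x file (plain or bgzipped)
#' and joins them to an external impact map that assigns each
#' (chrom, pos, ref, alt) site a gene symbol and a variant impact score.
#' Multiallelic sites must be pre-split (e.g. `bcftools norm -m-`); the
#' function refuses to guess allele-wise impact. Genotypes are read
#' phase-insensitively (`0/1` and `0|1` are identical); missing genotypes
#' are skipped and counted. When a site maps to several transcripts in
#' the impact map, the maximum (most damaging) score is kept.
#'
#' @param vcf Path to the VCF file.
#' @param impact_map Path to a TSV with columns
#'   `chrom, pos, ref, alt, gene, vis`.
#' @return Variant record frame as from [read_variant_table()], with
#'   `variant_id` set to `chrom:pos:ref:alt`. Attributes `n_unmapped`
#'   (variants absent from the impact map, dropped) and `n_missing_gt`
#'   (genotypes skipped) carry the conversion counts.
#' @export
vcf_to_variant_table <- function(vcf, impact_map) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required to read VCF input")
  }
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    warning("VCF contains no variant records")
  }
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multiallelic site at ", fix[which(grepl(",", alt))[1], "CHROM"],
         ":", fix[which(grepl(",", alt))[1], "POS"],
         "; split multiallelic records first (e.g. 'bcftools norm -m-')")
  }
  map <- utils::read.delim(impact_map, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "gene", "vis")
  if (!all(need %in% names(map))) {
    stop("impact map must have columns: ", paste(need, collapse = ", "))
  }
  # collapse per-transcript rows to the most damaging score per site
  map_key <- paste(map$chrom, map$pos, map$ref, map$alt, sep = ":")
  ord <- order(map_key, -map$vis)
  map <- map[ord, ][!duplicated(map_key[ord]), ]
  map_key <- paste(map$chrom, map$pos, map$ref, map$alt, sep = ":")

  site_key <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], alt, sep = ":")
  hit <- match(site_key, map_key)
  n_unmapped <- sum(is.na(hit))

  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  keep <- which(!is.na(hit))
  recs <- vector("list", length(keep))
  n_missing <- 0L
  for (k in seq_along(keep)) {
    i <- keep[k]
    g <- gsub("|", "/", gt[i, ], fixed = TRUE)
    zyg <- ifelse(g %in% "0/0", 0L,
                  ifelse(g %in% c("0/1", "1/0"), 1L,
                         ifelse(g %in% "1/1", 2L, NA_integer_)))
    miss <- is.na(zyg)
    n_missing <- n_missing + sum(miss)
    if (all(miss)) next
    m <- hit[i]
    recs[[k]] <- data.frame(sample_id = samples[!miss],
                            gene = toupper(map$gene[m]),
                            vis = map$vis[m],
                            zygosity = zyg[!miss],
                            variant_id = site_key[i],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), gene = character(0),
                      vis = numeric(0), zygosity = integer(0),
                      variant_id = character(0), stringsAsFactors = FALSE)
  }
  if (n_missing > 0) {
    warning(n_missing, " missing genotype(s) skipped")
  }
  out$inert <- out$zygosity == 0L
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_missing_gt") <- n_missing
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for Hardy-Weinberg equilibrium from biallelic
#' genotype counts. Conditional on the observed allele counts, the
#' probability of every admissible heterozygote count is computed, and
#' the p-value is the sum of probabilities of all configurations no more
#' probable than the observed one (two-sided by configuration
#' probability, the standard exact formulation).
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return The exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(5, 0, 0)   # monomorphic: p = 1
#' hwe_exact_test(0, 4, 1)
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0L) stop("zero individuals: HWE test undefined")
  n_a <- 2L * n_hom_ref + n_het   # reference allele count
  n_b <- 2L * n_hom_alt + n_het   # alternate allele count
  n_minor <- min(n_a, n_b)
  if (n_minor == 0L) return(1)
  # admissible heterozygote counts share the parity of the minor count
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  # P(het = h | n, n_minor) in log space:
  #   n! / (hom_maj! h! hom_min!) * 2^h * n_minor! n_major! / (2n)!
  n_major <- 2L * n - n_minor
  homs_min <- (n_minor - hets) / 2
  homs_maj <- n - hets - homs_min
  logp <- lgamma(n + 1) - lgamma(homs_maj + 1) - lgamma(hets + 1) -
    lgamma(homs_min + 1) + hets * log(2) +
    lgamma(n_minor + 1) + lgamma(n_major + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  if (length(obs) == 0L) {
    stop("observed genotype counts inconsistent with allele counts")
  }
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Apply site-level quality-control filters
#'
#' Removes variant sites failing the exact Hardy-Weinberg test in
#' controls (p below `hwe_threshold`) or with genotyping rate below
#' `rate_threshold` in cases, in controls, or in the combined cohort.
#' Genotyping rate at a site is the fraction of samples with a
#' non-missing genotype, i.e. with any record (including explicit
#' homozygous-reference, zygosity-0 rows) for that site. The HWE test is
#' computed on control samples only. Filtering is idempotent.
#'
#' @param records Variant record frame with a `variant_id` column.
#' @param phenotypes Named status vector as from [read_phenotypes()].
#' @param hwe_threshold HWE p-value below which a site is removed
#'   (default `5e-8`).
#' @param rate_threshold Minimum genotyping rate (default `0.95`).
#' @return The filtered record frame, with attribute `qc_report`: a list
#'   with the number of sites removed per rule and the removed site ids.
#' @export
apply_qc_filters <- function(records, phenotypes,
                             hwe_threshold = 5e-8,
                             rate_threshold = 0.95) {
  stopifnot(hwe_threshold > 0, hwe_threshold < 1,
            rate_threshold > 0, rate_threshold < 1)
  report <- list(n_sites = 0L, removed_hwe = character(0),
                 removed_rate = character(0), hwe_skipped = FALSE)
  if (nrow(records) == 0L) {
    attr(records, "qc_report") <- report
    return(records)
  }
  if (is.null(records$variant_id)) {
    stop("site-level QC requires a 'variant_id' column ",
         "(gene-level records carry no site identity)")
  }
  samp_status <- phenotypes[records$sample_id]
  if (anyNA(samp_status)) {
    stop("records contain samples absent from the phenotype table: ",
         records$sample_id[which(is.na(samp_status))[1]])
  }
  sites <- unique(records$variant_id)
  report$n_sites <- length(sites)
  n_case <- sum(phenotypes == "case")
  n_ctrl <- sum(phenotypes == "control")

  is_ctrl <- samp_status == "control"
  # genotyping rate per site per group (explicit records = non-missing)
  rate_of <- function(mask, denom) {
    if (denom == 0L) return(NULL)
    tab <- table(factor(records$variant_id[mask], levels = sites))
    as.numeric(tab) / denom
  }
  r_case <- rate_of(!is_ctrl, n_case)
  r_ctrl <- rate_of(is_ctrl, n_ctrl)
  r_all <- rate_of(rep(TRUE, nrow(records)), n_case + n_ctrl)
  low_rate <- r_all < rate_threshold
  if (!is.null(r_case)) low_rate <- low_rate | r_case < rate_threshold
  if (!is.null(r_ctrl)) low_rate <- low_rate | r_ctrl < rate_threshold
  report$removed_rate <- sites[low_rate]

  if (n_ctrl == 0L) {
    warning("no control samples: HWE filter skipped")
    report$hwe_skipped <- TRUE
    low_hwe <- rep(FALSE, length(sites))
  } else {
    ctrl_rec <- records[is_ctrl, , drop = FALSE]
    hwe_p <- vapply(sites, function(s) {
      z <- ctrl_rec$zygosity[ctrl_rec$variant_id == s]
      if (length(z) == 0L) return(1)
      hwe_exact_test(sum(z == 0L), sum(z == 1L), sum(z == 2L))
    }, numeric(1))
    low_hwe <- hwe_p < hwe_threshold
    report$removed_hwe <- sites[low_hwe]
  }
  drop_sites <- sites[low_hwe | low_rate]
  out <- records[!records$variant_id %in% drop_sites, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_report") <- report
  out
}
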