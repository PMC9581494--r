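test_that("variant tables parse, validate and round-trip", {
  tf <- write_tmp_variants(c("S1\tApoE\t1\t0.8", "S2\ttrem2\t2\t0.35"))
  rec <- read_variant_table(tf)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$gene, c("APOE", "TREM2"))  # symbols uppercased
  expect_equal(rec$vis, c(0.8, 0.35))
  expect_false(any(rec$inert))

  # zygosity 0 rows are kept but inert
  tf0 <- write_tmp_variants("S1\tA\t0\t0.5")
  expect_true(read_variant_table(tf0)$inert)

  # validation errors carry the offending row / column
  expect_error(read_variant_table(write_tmp_variants("S1\tA\t3\t0.5")),
               "zygosity.*row 1")
  expect_error(read_variant_table(write_tmp_variants("S1\tA\t1\t1.5")),
               "\\[0, 1\\].*row 1")
  expect_error(read_variant_table(
    write_tmp_variants("S1\tA\t1", header = "sample_id\tgene\tzygosity")),
    "missing required column 'vis'")

  # empty file with header: empty frame plus a warning
  expect_warning(rec0 <- read_variant_table(write_tmp_variants(character(0))),
                 "no records")
  expect_equal(nrow(rec0), 0)

  # write/read round trip preserves records, incl. alternate vis column
  out <- tempfile(fileext = ".tsv")
  write_variant_table(rec, out, vis_column = "ea")
  back <- read_variant_table(out, vis_column = "ea")
  expect_equal(back, rec)
})

test_that("phenotype tables accept 0/1 and case/control coding", {
  tf <- tempfile()
  writeLines(c("sample_id\tstatus", "S1\t1", "S2\t0", "S3\tcase"), tf)
  ph <- read_phenotypes(tf)
  expect_equal(unname(ph), c("case", "control", "case"))
  expect_equal(names(ph), c("S1", "S2", "S3"))
  writeLines(c("sample_id\tstatus", "S1\t2"), tf)
  expect_error(read_phenotypes(tf), "status")
  out <- tempfile()
  write_phenotypes(ph, out)
  expect_equal(read_phenotypes(out), ph)
})

test_that("VCF conversion decodes genotypes and joins the impact map", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0",
    "2\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/1\t0/1"), vcf)
  map <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tgene\tvis",
               "1\t100\tA\tG\tGENEA\t0.8",
               "1\t100\tA\tG\tGENEA\t0.6",   # second transcript, lower
               "1\t200\tC\tT\tGENEB\t0.4"), map)
  expect_warning(rec <- vcf_to_variant_table(vcf, map), "missing genotype")
  # site 2:300 not in map -> dropped and counted
  expect_equal(attr(rec, "n_unmapped"), 1L)
  expect_equal(attr(rec, "n_missing_gt"), 1L)
  r1 <- rec[rec$variant_id == "1:100:A:G", ]
  expect_equal(r1$zygosity[r1$sample_id == "S1"], 1L)  # 0/1
  expect_equal(r1$zygosity[r1$sample_id == "S2"], 2L)  # 1|1, phased alike
  expect_equal(unique(r1$vis), 0.8)  # max over transcripts
  r2 <- rec[rec$variant_id == "1:200:C:T", ]
  expect_equal(r2$sample_id, "S2")
  expect_equal(r2$zygosity, 0L)      # explicit hom-ref record, inert
  expect_true(r2$inert)

  # round-trips through the TSV reader unchanged
  out <- tempfile(fileext = ".tsv")
  write_variant_table(rec, out)
  back <- read_variant_table(out)
  expect_equal(back[names(rec)], as.data.frame(rec),
               ignore_attr = TRUE)

  # multiallelic sites are refused
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(vcf_to_variant_table(vcf, map), "multiallelic")
})

test_that("exact HWE test matches enumeration for all tables n <= 10", {
  expect_equal(hwe_exact_test(5, 0, 0), 1)           # monomorphic
  expect_equal(hwe_exact_test(0, 4, 1), 3 / 7, tolerance = 1e-12)
  for (n in 1:10) {
    for (a in 0:n) for (b in 0:(n - a)) {
      c <- n - a - b
      expect_equal(hwe_exact_test(a, b, c), hwe_oracle(a, b, c),
                   tolerance = 1e-10,
                   label = sprintf("hwe(%d,%d,%d)", a, b, c))
    }
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero individuals")
})

test_that("QC filters remove HWE and low-rate sites and are idempotent", {
  samples <- sprintf("S%02d", 1:20)
  ph <- setNames(rep(c("case", "control"), each = 10), samples)
  # site BAD_HWE: controls all het -> strong HWE violation
  # site LOW_RATE: genotyped in half the cohort only
  # site GOOD: genotyped everywhere, equilibrium-ish in controls
  rec <- rbind(
    data.frame(sample_id = samples, gene = "G1", vis = 0.5,
               zygosity = rep(1L, 20), variant_id = "BAD_HWE"),
    data.frame(sample_id = samples[1:10], gene = "G2", vis = 0.5,
               zygosity = 1L, variant_id = "LOW_RATE"),
    data.frame(sample_id = samples, gene = "G3", vis = 0.5,
               zygosity = rep(c(0L, 1L), 10), variant_id = "GOOD"))
  rec$inert <- rec$zygosity == 0L
  # p for 10 all-het controls is below a loose threshold
  expect_lt(hwe_exact_test(0, 10, 0), 0.05)
  filt <- apply_qc_filters(rec, ph, hwe_threshold = 0.05,
                           rate_threshold = 0.95)
  rep <- attr(filt, "qc_report")
  expect_equal(rep$removed_hwe, "BAD_HWE")
  expect_equal(rep$removed_rate, "LOW_RATE")
  expect_equal(unique(filt$variant_id), "GOOD")
  # idempotent
  again <- apply_qc_filters(filt, ph, hwe_threshold = 0.05,
                            rate_threshold = 0.95)
  expect_equal(as.data.frame(again), as.data.frame(filt),
               ignore_attr = TRUE)
  # genotyping rate 96% in every group is retained at threshold 0.95
  big <- sprintf("B%02d", 1:50)
  ph_big <- setNames(rep(c("case", "control"), each = 25), big)
  rec96 <- data.frame(sample_id = big[c(1:24, 26:49)],  # 24/25 per group
                      gene = "G4", vis = 0.2, zygosity = 0L,
                      variant_id = "R96", inert = TRUE)
  filt96 <- apply_qc_filters(rec96, ph_big, rate_threshold = 0.95)
  expect_true("R96" %in% filt96$variant_id)

  # degenerate inputs
  empty <- rec[0, ]
  out <- apply_qc_filters(empty, ph)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "qc_report")$n_sites, 0L)
  # no controls: HWE skipped with warning
  ph_cases <- setNames(rep("case", 20), samples)
  expect_warning(apply_qc_filters(rec, ph_cases), "HWE filter skipped")
  # gene-level records without site identity cannot be QC'd
  expect_error(apply_qc_filters(rec[, setdiff(names(rec), "variant_id")],
                                ph), "variant_id")
})
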