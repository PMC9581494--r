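test_that("simulated networks are reproducible with a local module", {
  cfg <- simulation_config(seed = 5)
  n1 <- simulate_network(cfg)
  n2 <- simulate_network(cfg)
  expect_identical(n1$network$edges, n2$network$edges)
  expect_identical(n1$module, n2$module)
  expect_length(n1$module, 25)
  # scale-free degree distribution is heavy-tailed
  deg <- igraph::degree(as_igraph(n1$network))
  expect_gt(max(deg), 5 * stats::median(deg))
  # module genes are mutually proximate: pairwise distance <= 2
  g <- as_igraph(n1$network)
  dm <- igraph::distances(g, v = n1$module, to = n1$module)
  expect_lte(max(dm), 2)
  # other network models produce valid connected networks
  for (model in c("stochastic-block", "small-world")) {
    cfgm <- simulation_config(n_genes = 200, module_size = 10,
                              model = model, seed = 8)
    nm <- simulate_network(cfgm)
    expect_equal(igraph::count_components(as_igraph(nm$network)), 1)
    expect_true(all(nm$module %in% nm$network$genes))
  }
  expect_error(simulate_network(
    simulation_config(n_genes = 20, module_size = 19, seed = 1,
                      model = "stochastic-block")), "module_size")
})

test_that("simulated cohorts implant a case-only module signal", {
  cfg <- simulation_config(n_genes = 120, module_size = 10,
                           n_case = 120, n_ctrl = 120, seed = 3)
  net <- simulate_network(cfg)
  coh <- simulate_cohort(net$network, net$module, cfg)
  expect_equal(sum(coh$phenotypes == "case"), 120)
  expect_true(all(coh$records$vis >= 0 & coh$records$vis <= 1))
  expect_true(all(coh$records$zygosity %in% 1:2))
  ps <- build_ps_matrix(coh$records, coh$phenotypes, net$network$genes)
  mod <- rownames(ps) %in% net$module
  case_cols <- coh$phenotypes == "case"
  # module genes are more perturbed in cases; background genes are not
  expect_gt(mean(ps[mod, case_cols]), mean(ps[mod, !case_cols]) + 0.1)
  expect_lt(abs(mean(ps[!mod, case_cols]) - mean(ps[!mod, !case_cols])),
            0.02)
  # null configuration: cases and controls exchangeable
  cfg0 <- simulation_config(n_genes = 120, module_size = 10,
                            n_case = 120, n_ctrl = 120,
                            rate_multiplier = 1, case_vis_shape = NULL,
                            seed = 3)
  coh0 <- simulate_cohort(net$network, net$module, cfg0)
  ps0 <- build_ps_matrix(coh0$records, coh0$phenotypes,
                         net$network$genes)
  expect_lt(abs(mean(ps0[mod, case_cols]) - mean(ps0[mod, !case_cols])),
            0.03)
  # rate 0: empty table with a warning
  cfg_empty <- simulation_config(n_genes = 50, module_size = 5,
                                 n_case = 5, n_ctrl = 5,
                                 variant_rate = 0, rate_multiplier = 0,
                                 seed = 2)
  netx <- simulate_network(cfg_empty)
  expect_warning(coh_e <- simulate_cohort(netx$network, netx$module,
                                          cfg_empty), "no variants")
  expect_equal(nrow(coh_e$records), 0)
  # records round-trip through the variant-table dialect
  tf <- tempfile(fileext = ".tsv")
  write_variant_table(coh$records, tf)
  expect_equal(read_variant_table(tf), coh$records)
})

test_that("edge perturbation respects counts, seeds and restriction", {
  cfg <- simulation_config(n_genes = 200, module_size = 10, seed = 4)
  net <- simulate_network(cfg)$network
  E <- nrow(net$edges)
  # identity
  p0 <- perturb_edges(net, 0, 0)
  expect_identical(p0$edges, net$edges)
  # exact deletion count, deterministic under a seed
  p1 <- perturb_edges(net, delete_frac = 0.5, seed = 7)
  expect_equal(nrow(p1$edges), E - round(0.5 * E))
  expect_identical(perturb_edges(net, delete_frac = 0.5, seed = 7)$edges,
                   p1$edges)
  # additions: exact count, no duplicates, no self loops
  p2 <- perturb_edges(net, add_frac = 0.3, seed = 7)
  expect_equal(nrow(p2$edges), E + round(0.3 * E))
  key <- paste(p2$edges[, 1], p2$edges[, 2])
  expect_false(any(duplicated(key)))
  expect_false(any(p2$edges[, 1] == p2$edges[, 2]))
  # restricted deletion only touches edges incident to the given set
  genes <- net$genes[net$edges[1:3, 1]]
  p3 <- perturb_edges(net, delete_frac = 0.02, restrict_to = genes,
                      seed = 1)
  gone <- setdiff(paste(net$edges[, 1], net$edges[, 2]),
                  paste(p3$edges[, 1], p3$edges[, 2]))
  idx <- which(net$genes %in% genes)
  for (e in gone) {
    ij <- as.integer(strsplit(e, " ")[[1]])
    expect_true(any(ij %in% idx))
  }
})

test_that("recovery metrics behave at the extremes", {
  sc <- data.frame(gene = paste0("g", 1:10),
                   distance = c(10:8, -(7:1), 0.5)[1:10] / 10,
                   candidate = c(rep(TRUE, 3), rep(FALSE, 7)))
  truth <- paste0("g", 1:3)
  ev <- evaluate_recovery(sc, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$auroc, 1)
  # disjoint candidates
  sc$candidate <- c(rep(FALSE, 7), rep(TRUE, 3))
  ev2 <- evaluate_recovery(sc, truth)
  expect_equal(ev2$precision, 0)
  expect_equal(ev2$recall, 0)
  expect_error(evaluate_recovery(sc, "absent"), "no overlap")
  # random ranking: AUROC near 1/2 on average
  set.seed(12)
  aucs <- replicate(40, {
    sc$distance <- rnorm(10)
    evaluate_recovery(sc, truth)$auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
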