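test_that("weighted Laplacian spectra match closed forms", {
  # 2-node graph with unit weight: eigenvalues {0, 2}
  g2 <- make_graph(make_net(2, edge_mat(1, 2)))
  d2 <- weighted_laplacian(g2)
  expect_equal(d2$values, c(0, 2), tolerance = 1e-12)
  # path P3, unit weights: {0, 1, 3}
  d3 <- weighted_laplacian(make_graph(path_net(3)))
  expect_equal(d3$values, c(0, 1, 3), tolerance = 1e-10)
  # smallest eigenvalue 0 with a constant eigenvector, V orthonormal
  gr <- random_connected_graph(30, seed = 5)
  dec <- weighted_laplacian(gr)
  expect_lt(abs(dec$values[1]), 1e-10)
  expect_gte(min(dec$values), -1e-10)
  v1 <- dec$vectors[, 1]
  expect_lt(diff(range(v1)), 1e-8)
  expect_equal(crossprod(dec$vectors), diag(30), tolerance = 1e-8,
               ignore_attr = TRUE)
  gr$weights[1] <- NaN
  expect_error(weighted_laplacian(gr), "non-finite")
})

test_that("automatic scales follow the spectral heuristic", {
  dec <- structure(list(values = c(0, 0.1, 10)), class = "spectral_decomposition")
  s <- auto_scales(dec, eta = c(0.95, 0.80), J = 2)
  expect_equal(s, c(-log(0.95), -log(0.80)), tolerance = 1e-10)
  expect_equal(auto_scales(dec, J = 1), mean(c(-log(0.95), -log(0.8))))
  expect_true(all(auto_scales(dec, J = 5) > 0))
  # zero-weight edges may decouple the weighted graph: the smallest
  # positive eigenvalue takes over as the scale reference
  dec0 <- structure(list(values = c(0, 0, 4)), class = "spectral_decomposition")
  expect_equal(auto_scales(dec0, J = 2), c(-log(0.95), -log(0.8)) / 4)
  # an all-zero spectrum (no edges with weight) is refused
  dec_null <- structure(list(values = c(0, 0, 0)), class = "spectral_decomposition")
  expect_error(auto_scales(dec_null), "all zero")
})

test_that("heat wavelets match the 2-node closed form and conserve mass", {
  dec <- weighted_laplacian(make_graph(make_net(2, edge_mat(1, 2))))
  Psi <- heat_wavelets(dec, s = 1)
  on_diag <- (1 + exp(-2)) / 2
  off_diag <- (1 - exp(-2)) / 2
  expect_equal(Psi, matrix(c(on_diag, off_diag, off_diag, on_diag), 2),
               tolerance = 1e-12)
  # s -> 0 limit: identity
  expect_equal(heat_wavelets(dec, 1e-14), diag(2), tolerance = 1e-8)
  # symmetry + unit column sums on random connected weighted graphs
  for (seed in 1:5) {
    gr <- random_connected_graph(sample(5:40, 1), seed)
    dec <- weighted_laplacian(gr)
    for (s in c(0.05, 0.5, 2)) {
      P <- heat_wavelets(dec, s)
      expect_equal(P, t(P), tolerance = 1e-10)
      expect_equal(colSums(P), rep(1, ncol(P)), tolerance = 1e-8)
    }
  }
})

test_that("wavelets are invariant to eigenvector sign flips", {
  gr <- random_connected_graph(12, seed = 9)
  dec <- weighted_laplacian(gr)
  flipped <- dec
  flipped$vectors[, c(2, 5)] <- -flipped$vectors[, c(2, 5)]
  expect_equal(heat_wavelets(dec, 0.7), heat_wavelets(flipped, 0.7),
               tolerance = 1e-12)
})

test_that("characteristic function values match the dense oracle", {
  dec <- weighted_laplacian(make_graph(make_net(2, edge_mat(1, 2))))
  Psi <- heat_wavelets(dec, s = 1)
  emb <- characteristic_embedding(Psi, t_grid = c(0, 1))
  # t = 0 gives (Re, Im) = (1, 0) for every node
  expect_equal(emb[, 1], rep(1, 2))
  expect_equal(emb[, 2], rep(0, 2))
  # t = 1: phi = (exp(i * Psi_11) + exp(i * Psi_21)) / 2
  phi <- mean(exp(1i * 1 * Psi[, 1]))
  expect_equal(emb[1, 3], Re(phi), tolerance = 1e-12)
  expect_equal(emb[1, 4], Im(phi), tolerance = 1e-12)
  expect_equal(Re(phi), 0.8756, tolerance = 1e-4)
  expect_equal(Im(phi), 0.4783, tolerance = 1e-4)
  # |phi| <= 1 everywhere on a bigger random graph
  gr <- random_connected_graph(25, seed = 3)
  e <- embed_graph(gr, embedding_config(J = 2, d = 20, t_max = 60))
  mods <- sqrt(e[, seq(1, ncol(e), 2)]^2 + e[, seq(2, ncol(e), 2)]^2)
  expect_lte(max(mods), 1 + 1e-12)
  # grid must start at 0
  expect_error(characteristic_embedding(Psi, c(1, 2)), "t_grid")
})

test_that("structurally equivalent nodes embed identically", {
  cfg <- embedding_config()
  # path ends
  ep <- embed_graph(make_graph(path_net(6)), cfg)
  expect_equal(ep[1, ], ep[6, ], tolerance = 1e-8)
  # all leaves of a star
  es <- embed_graph(make_graph(star_net(5)), cfg)
  for (leaf in 3:6) {
    expect_equal(es[2, ], es[leaf, ], tolerance = 1e-8)
  }
  # mirrored nodes of a barbell with equal weights
  eb <- embed_graph(make_graph(barbell_net(4)), cfg)
  expect_equal(eb[1, ], eb[5, ], tolerance = 1e-8)  # bridge heads
  expect_equal(eb[2, ], eb[6, ], tolerance = 1e-8)  # mirrored clique nodes
  expect_equal(eb[2, ], eb[3, ], tolerance = 1e-8)  # within-clique twins
})

test_that("embeddings are permutation-equivariant and reproducible", {
  gr <- random_connected_graph(15, seed = 21)
  cfg <- embedding_config(J = 2, d = 25, t_max = 50)
  e1 <- embed_graph(gr, cfg)
  # identical graphs give identical embeddings row by row
  expect_identical(e1, embed_graph(gr, cfg))
  # relabel nodes: rows permute identically
  perm <- sample(15)
  net_p <- make_net(15, cbind(perm[gr$network$edges[, 1]],
                              perm[gr$network$edges[, 2]]))
  net_p$edges <- cbind(pmin(net_p$edges[, 1], net_p$edges[, 2]),
                       pmax(net_p$edges[, 1], net_p$edges[, 2]))
  gr_p <- make_graph(net_p, gr$weights)
  e2 <- embed_graph(gr_p, cfg)
  expect_equal(e2[perm, ], e1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("paired embedding shares scales and handles components", {
  # two components: a P4 and a triangle; both large enough to embed,
  # plus an isolated edge that is excluded
  net <- make_net(9, edge_mat(1, 2, 2, 3, 3, 4, 5, 6, 6, 7, 5, 7, 8, 9))
  w_case <- c(1, 1, 1, 2, 2, 2, 1)
  w_ctrl <- c(1, 1, 1, 1, 1, 1, 1)
  pair <- perturbnet:::embed_cohort_pair(
    make_graph(net, w_case, "case"), make_graph(net, w_ctrl, "control"),
    embedding_config(d = 10, t_max = 20), min_component = 3)
  expect_equal(nrow(pair$case), 7)  # components of size 4 and 3
  expect_equal(sort(pair$excluded_genes), c("N08", "N09"))
  expect_equal(length(pair$scales), 2)
  # control embedded with scales from the case graph: where the case
  # weights differ the embeddings differ, and feature 1 is Re phi(0)=1
  expect_equal(unname(pair$case[, 1]), rep(1, 7))
  expect_false(isTRUE(all.equal(pair$case[5, ], pair$control[5, ])))
})
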