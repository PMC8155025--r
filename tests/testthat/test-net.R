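# The MPNN parameterization: embeddings, neighborhoods, layer updates,
# projection heads, conditioner, and the invariances they must satisfy.

test_that("node embeddings are sums of per-property table rows", {
  v <- toy_vocab()
  params <- init_params(v, model_config(d0 = 16L, L = 1L), seed = 2)
  g <- smiles_to_graph("CCO", v)
  b <- maskmol:::build_batch(list(g), v)
  fw <- maskmol:::forward_batch(params, b, want_cache = TRUE)
  hv0 <- fw$cache$layers[[1]]$hv_in
  manual <- Reduce(`+`, lapply(1:6, function(k)
    params$par[[paste0("emb_node_", k)]][g$nodes[, k], , drop = FALSE]))
  expect_equal(hv0, manual, tolerance = 1e-12)
  # identical property vectors give identical embeddings (benzene carbons)
  gb <- smiles_to_graph("c1ccccc1", v)
  bb <- maskmol:::build_batch(list(gb), v)
  hvb <- maskmol:::forward_batch(params, bb, want_cache = TRUE)$cache$layers[[1]]$hv_in
  expect_equal(hvb[1, ], hvb[2, ], tolerance = 1e-12)

  # fully masked node embeds as the sum of MASK rows
  mg <- mask_graph(g, 1, v, seed = 1)$graph
  bm <- maskmol:::build_batch(list(mg), v)
  fwm <- maskmol:::forward_batch(params, bm, want_cache = TRUE)
  mask_sum <- Reduce(`+`, lapply(1:6, function(k) {
    tab <- params$par[[paste0("emb_node_", k)]]
    tab[nrow(tab), ]
  }))
  expect_equal(fwm$cache$layers[[1]]$hv_in[1, ], mask_sum, tolerance = 1e-12)

  # changing only the atom type shifts the embedding by a table-row difference
  g2 <- g; g2$nodes[1, "atom_type"] <- g$nodes[3, "atom_type"]
  b2 <- maskmol:::build_batch(list(g2), v)
  hv2 <- maskmol:::forward_batch(params, b2, want_cache = TRUE)$cache$layers[[1]]$hv_in
  W1 <- params$par$emb_node_1
  expect_equal(hv2[1, ] - hv0[1, ],
               W1[g$nodes[3, 1], ] - W1[g$nodes[1, 1], ], tolerance = 1e-12)
})

test_that("neighborhoods follow the masked-or-bonded rule", {
  v <- toy_vocab()
  g <- smiles_to_graph("CCO", v)
  expect_identical(neighborhood(g, 2), c(1L, 3L))
  expect_identical(neighborhood(g, 1), 2L)
  # all pairs no-bond -> empty neighborhoods
  iso <- maskmol:::new_graph(rbind(g$nodes[1, , drop = FALSE],
                                   g$nodes[1, , drop = FALSE]), 1L)
  expect_identical(neighborhood(iso, 1), integer(0))
  # fully masked edges on 4 nodes -> complete neighborhoods
  g4 <- smiles_to_graph("CC(=O)N", v)
  mg <- mask_graph(g4, 1, v, seed = 1)$graph
  for (i in 1:4) expect_length(neighborhood(mg, i), 3L)
})

test_that("forward outputs live on probability simplices over real categories", {
  v <- toy_vocab()
  params <- init_params(v, model_config(d0 = 24L, L = 2L), seed = 5)
  g <- mask_graph(smiles_to_graph("CC(=O)N", v), 0.3, v, seed = 4)$graph
  fw <- mgm_forward(g, params)
  for (k in 1:6) {
    expect_identical(ncol(fw$node[[k]]), vocab_n_categories(v, k))  # MASK excluded
    expect_true(all(fw$node[[k]] >= 0))
    expect_true(all(abs(rowSums(fw$node[[k]]) - 1) < 1e-6))
  }
  expect_identical(ncol(fw$edge), 5L)
  expect_true(all(abs(rowSums(fw$edge) - 1) < 1e-6))
})

test_that("zeroed projection heads yield uniform distributions", {
  v <- toy_vocab()
  params <- init_params(v, model_config(d0 = 16L, L = 1L), seed = 3)
  for (k in 1:6) {
    params$par[[paste0("head_n", k, "_W2")]][] <- 0
    params$par[[paste0("head_n", k, "_b2")]][] <- 0
  }
  fw <- mgm_forward(smiles_to_graph("CCO", v), params)
  for (k in 1:6) {
    expect_equal(unname(fw$node[[k]][1, ]),
                 rep(1 / vocab_n_categories(v, k), vocab_n_categories(v, k)),
                 tolerance = 1e-12)
  }
})

test_that("forward is deterministic and permutation equivariant", {
  v <- toy_vocab()
  params <- init_params(v, model_config(d0 = 32L, L = 3L), seed = 8)
  g <- mask_graph(smiles_to_graph("c1ccccc1", v), 0.25, v, seed = 21)$graph
  fw1 <- mgm_forward(g, params)
  fw1b <- mgm_forward(g, params)
  expect_identical(fw1, fw1b)

  set.seed(13)
  perm <- sample(g$n)
  fw2 <- mgm_forward(relabel_graph(g, perm), params)
  for (k in 1:6) {
    expect_equal(fw2$node[[k]][perm, , drop = FALSE], fw1$node[[k]],
                 tolerance = 1e-10)
  }
  pr <- graph_pairs(g$n)
  expect_equal(fw2$edge[pair_index(perm[pr[, 1]], perm[pr[, 2]], g$n), , drop = FALSE],
               fw1$edge, tolerance = 1e-10)
})

test_that("an isolated node reduces to LayerNorm(GRU(h, 0))", {
  v <- toy_vocab()
  params <- init_params(v, model_config(d0 = 8L, L = 1L), seed = 6)
  g <- smiles_to_graph("C", v)
  b <- maskmol:::build_batch(list(g), v)
  fw <- maskmol:::forward_batch(params, b, want_cache = TRUE)
  p <- params$par
  h <- fw$cache$layers[[1]]$hv_in[1, ]
  u <- rep(0, 8)
  r <- 1 / (1 + exp(-(u %*% p$gru_Wr + h %*% p$gru_Ur + p$gru_br)))
  z <- 1 / (1 + exp(-(u %*% p$gru_Wz + h %*% p$gru_Uz + p$gru_bz)))
  nn <- tanh(u %*% p$gru_Wn + p$gru_bn1 + r * (h %*% p$gru_Un + p$gru_bn2))
  go <- (1 - z) * nn + z * h
  xc <- go - mean(go)
  xh <- xc / sqrt(mean(xc^2) + 1e-5)
  expect_equal(as.numeric(xh * p$ln_g + p$ln_b), fw$hv_top[1, ], tolerance = 1e-10)
  expect_equal(fw$cache$layers[[1]]$u[1, ], u, tolerance = 1e-12)
})

test_that("the conditioner shifts output distributions", {
  v <- toy_vocab()
  params <- init_params(v, model_config(d0 = 16L, L = 2L, conditional = TRUE,
                                        property_name = "mol_weight"), seed = 4)
  params$meta$y_mean <- 50; params$meta$y_sd <- 20
  g <- mask_graph(smiles_to_graph("CCO", v), 0.3, v, seed = 2)$graph
  lo <- mgm_forward(g, params, y = 20)
  hi <- mgm_forward(g, params, y = 90)
  diff <- max(abs(unlist(lo$node) - unlist(hi$node)))
  expect_gt(diff, 1e-6)
  expect_error(mgm_forward(g, params), "requires y")
})

test_that("property standardization matches direct arithmetic", {
  expect_identical(standardize_property(5, 5, 2), 0)
  expect_identical(standardize_property(7, 5, 2), 1)
  ys <- c(12.3, 45.1, 8.8, 30.0, 22.2)
  m <- mean(ys); s <- stats::sd(ys)
  expect_equal(standardize_property(ys, m, s), (ys - m) / s, tolerance = 1e-12)
  expect_error(standardize_property(1, 0, 0), "must be > 0")
})
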