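# Vocabulary construction and SMILES <-> graph conversion.

test_that("vocabulary covers observed values plus MASK, with fixed panels", {
  v <- build_vocabulary(c("C", "N", "O", "F"))
  expect_identical(v$node$atom_type$categories, c("C", "F", "N", "O"))
  expect_length(v$node$atom_type$categories, 4L)  # QM9 element panel: T = 4
  expect_identical(v$node$charge$categories, 0L)
  expect_identical(v$node$chirality$categories,
                   c("unspecified", "cw", "ccw", "other"))
  expect_identical(v$node$in_ring$categories, c(FALSE, TRUE))
  expect_identical(v$edge$categories,
                   c("none", "single", "double", "triple", "aromatic"))
  # MASK is always the extra final index
  for (k in 1:6) {
    expect_identical(v$node[[k]]$mask_index,
                     length(v$node[[k]]$categories) + 1L)
  }
  expect_identical(v$edge$mask_index, 6L)
})

test_that("single-molecule vocabulary is that molecule's values", {
  v <- build_vocabulary("C")
  expect_identical(v$node$atom_type$categories, "C")
  expect_identical(v$node$num_h$categories, 4L)
  expect_identical(v$node$charge$categories, 0L)
})

test_that("vocabulary construction errors name the offending line", {
  expect_error(build_vocabulary(c("C", "xyz", "O")), "line\\(s\\) 2")
  expect_error(build_vocabulary(character(0)), "empty")
})

test_that("vocabulary JSON round-trips", {
  v <- toy_vocab()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  vocab_write_json(v, path)
  v2 <- vocab_read_json(path)
  expect_identical(v2$node$atom_type$categories, v$node$atom_type$categories)
  expect_identical(v2$node$num_h$categories, v$node$num_h$categories)
  expect_identical(v2$edge$mask_index, v$edge$mask_index)
})

test_that("pair storage covers exactly N(N-1)/2 slots and indices agree", {
  for (n in c(2L, 3L, 5L, 9L)) {
    pr <- graph_pairs(n)
    expect_identical(nrow(pr), (n * (n - 1L)) %/% 2L)
    expect_true(all(pr[, "i"] < pr[, "j"]))
    expect_identical(pair_index(pr[, "i"], pr[, "j"], n), seq_len(nrow(pr)))
    expect_identical(pair_index(pr[, "j"], pr[, "i"], n), seq_len(nrow(pr)))
  }
  expect_identical(nrow(graph_pairs(1L)), 0L)
})

test_that("smiles_to_graph featurizes single atoms and chains", {
  v <- toy_vocab()
  g <- smiles_to_graph("C", v)
  expect_identical(g$n, 1L)
  expect_identical(length(g$edges), 0L)
  expect_identical(v$node$atom_type$categories[g$nodes[, "atom_type"]], "C")
  expect_identical(v$node$num_h$categories[g$nodes[, "num_h"]], 4L)
  expect_identical(v$node$charge$categories[g$nodes[, "charge"]], 0L)
  expect_identical(v$node$chirality$categories[g$nodes[, "chirality"]], "unspecified")
  expect_false(v$node$in_ring$categories[g$nodes[, "in_ring"]])
  expect_false(v$node$aromatic$categories[g$nodes[, "aromatic"]])

  g3 <- smiles_to_graph("CCO", v)
  expect_identical(g3$n, 3L)
  expect_identical(length(g3$edges), 3L)
  # two single bonds and one no-bond prospective pair
  types <- MGM_EDGE_TYPES[g3$edges]
  expect_identical(sum(types == "single"), 2L)
  expect_identical(sum(types == "none"), 1L)
})

test_that("aromatic rings keep a distinct edge category", {
  v <- toy_vocab()
  g <- smiles_to_graph("c1ccccc1", v)
  expect_identical(g$n, 6L)
  expect_identical(sum(g$edges == match("aromatic", MGM_EDGE_TYPES)), 6L)
  expect_identical(sum(g$edges == 1L), 9L)
  expect_true(all(v$node$aromatic$categories[g$nodes[, "aromatic"]]))
  expect_true(all(v$node$in_ring$categories[g$nodes[, "in_ring"]]))
})

test_that("graphs round-trip to canonical SMILES across a corpus", {
  v <- toy_vocab()
  gs <- toy_graphs()
  back <- graphs_to_smiles(gs, v)
  expect_identical(back, chem_canonicalize(toy_smiles()))
})

test_that("equivalent SMILES spellings canonicalize to one graph image", {
  v <- toy_vocab()
  g1 <- smiles_to_graph("CCO", v)
  g2 <- smiles_to_graph("OCC", v)
  expect_identical(graph_to_smiles(g1, v), graph_to_smiles(g2, v))
})

test_that("chemically impossible graphs fail sanitization, not repair", {
  v <- build_vocabulary("C")
  v$node$num_h$categories <- c(4L, 5L)  # admit an impossible hydrogen count
  v$node$num_h$mask_index <- 3L
  g <- maskmol:::new_graph(
    cbind(atom_type = 1L, num_h = 2L, charge = 1L, chirality = 1L,
          in_ring = 1L, aromatic = 1L), integer(0))
  expect_true(is.na(graph_to_smiles(g, v)))
})

test_that("disconnected graphs serialize as multi-fragment SMILES", {
  v <- toy_vocab()
  gC <- smiles_to_graph("C", v)
  g2 <- maskmol:::new_graph(rbind(gC$nodes, gC$nodes), 1L)  # two methanes, no bond
  expect_identical(graph_to_smiles(g2, v), "C.C")
})

test_that("MASK in a graph is a contract violation, not invalidity", {
  v <- toy_vocab()
  g <- smiles_to_graph("CCO", v)
  mg <- mask_graph(g, 1, v)$graph
  expect_error(graph_to_smiles(mg, v), "MASK")
})

test_that("out-of-vocabulary values are vocabulary errors", {
  v <- build_vocabulary(c("C", "O"))
  expect_error(smiles_to_graph("CN", v), "vocabulary")
  expect_error(smiles_to_graph("not-a-smiles", v), "parse")
})

test_that("graph molecular weight matches the descriptor oracle", {
  v <- toy_vocab()
  smi <- c("C", "CCO", "CC(=O)N")
  gw <- vapply(smiles_to_graphs(smi, v), graph_mol_weight, numeric(1), vocab = v)
  oracle <- chem_descriptors(smi)$MolWt
  expect_equal(gw, oracle, tolerance = 1e-3)
})
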