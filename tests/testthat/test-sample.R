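# Marginals, initialization strategies, and the masked-resampling sampler.

test_that("empirical marginals are exact frequencies", {
  v <- build_vocabulary(c("CCO", "C"))
  ds <- dataset_from_smiles(c("CCO"), vocab = v); ds$vocab <- v
  m <- estimate_marginals(ds)
  expect_equal(m$edge, c(1 / 3, 2 / 3, 0, 0, 0), tolerance = 1e-12)

  ds1 <- dataset_from_smiles("C", vocab = v); ds1$vocab <- v
  m1 <- estimate_marginals(ds1)
  expect_equal(m1$node$atom_type[match("C", v$node$atom_type$categories)], 1)

  ds4 <- fixture4_dataset()
  m4 <- estimate_marginals(ds4)
  for (k in 1:6) expect_equal(sum(m4$node[[k]]), 1, tolerance = 1e-12)
  expect_equal(sum(m4$edge), 1, tolerance = 1e-12)
  expect_equal(sum(m4$node_count$probs), 1, tolerance = 1e-12)
  expect_error(estimate_marginals(new_dataset <- structure(
    list(graphs = list(), vocab = v), class = "mgm_dataset")), "empty")
})

test_that("training initialization draws training graphs", {
  v <- build_vocabulary("CCO")
  ds <- dataset_from_smiles("CCO", vocab = v); ds$vocab <- v
  g <- init_graph("training", ds, seed = 4)
  expect_identical(g$nodes, ds$graphs[[1]]$nodes)
  expect_identical(g$edges, ds$graphs[[1]]$edges)
})

test_that("marginal initialization is exact for point masses and unbiased otherwise", {
  v <- build_vocabulary("CCO")
  point <- structure(list(
    node = lapply(1:6, function(k) {
      p <- rep(0, vocab_n_categories(v, k)); p[1] <- 1; p
    }),
    edge = c(0, 1, 0, 0, 0),
    node_count = list(values = 3L, probs = 1)), class = "mgm_marginals")
  g <- init_graph("marginal", point, seed = 2)
  expect_identical(g$n, 3L)
  expect_true(all(g$nodes == 1L))
  expect_true(all(g$edges == 2L))

  ds <- fixture4_dataset()
  marg <- estimate_marginals(ds)
  set.seed(19)
  draws <- replicate(3000, init_graph("marginal", marg), simplify = FALSE)
  edges <- unlist(lapply(draws, `[[`, "edges"))
  phat <- tabulate(edges, 5) / length(edges)
  se <- sqrt(marg$edge * (1 - marg$edge) / length(edges))
  expect_true(all(abs(phat - marg$edge) <= 3 * se + 1e-9))
})

test_that("generate_step changes at most the masked slot budget", {
  ds <- fixture4_dataset()
  v <- ds$vocab
  params <- init_params(v, model_config(d0 = 16L, L = 2L), seed = 3)
  g <- ds$graphs[[which(vapply(ds$graphs, `[[`, integer(1), "n") == 4L)[1]]]
  s_tot <- 6L * 4L + 6L
  for (alpha in c(0.1, 0.3)) {
    out <- generate_step(g, params, alpha, seed = 8)
    expect_false(maskmol:::graph_has_mask(out, v))
    changed <- sum(out$nodes != g$nodes) + sum(out$edges != g$edges)
    expect_lte(changed, ceiling(alpha * s_tot))
  }
  expect_warning(out0 <- generate_step(g, params, 0), "identity")
  expect_identical(out0, g)
})

test_that("trajectories have length K+1, honor K=0, and are seed-deterministic", {
  ds <- fixture4_dataset()
  params <- init_params(ds$vocab, model_config(d0 = 16L, L = 2L), seed = 3)
  cfg0 <- sampler_config(init = "training", alpha = 0.2, K = 0L, seed = 5)
  tr0 <- generate(params, cfg0, ds, n_samples = 2L)
  expect_identical(names(tr0$snapshots), "0")

  cfg <- sampler_config(init = "training", alpha = 0.2, K = 7L, seed = 5)
  tr <- generate(params, cfg, ds, n_samples = 3L)
  expect_length(tr$snapshots, 8L)  # K + 1 including initialization
  tr2 <- generate(params, cfg, ds, n_samples = 3L)
  expect_identical(tr$final, tr2$final)
  expect_identical(tr$snapshots, tr2$snapshots)

  # record_every subsets the kept snapshots without changing the chain
  cfgr <- sampler_config(init = "training", alpha = 0.2, K = 7L,
                         record_every = c(0L, 7L), seed = 5)
  trr <- generate(params, cfgr, ds, n_samples = 3L)
  expect_identical(names(trr$snapshots), c("0", "7"))
  expect_identical(trr$final, tr$final)
})

test_that("sampler defaults follow the QM9-scale configuration", {
  cfg <- sampler_config()
  expect_identical(cfg$K, 400L)
  expect_identical(cfg$alpha, 0.1)
  expect_identical(cfg$temperature, 1)
  expect_error(sampler_config(K = -1), "K >= 0")
  expect_warning(sampler_config(alpha = 0, K = 10L), "identity")
})

test_that("trajectory snapshots serialize as SMILES files with a manifest", {
  ds <- fixture4_dataset()
  params <- init_params(ds$vocab, model_config(d0 = 16L, L = 2L), seed = 3)
  cfg <- sampler_config(init = "training", alpha = 0.1, K = 2L,
                        record_every = c(0L, 2L), seed = 9)
  tr <- generate(params, cfg, ds, n_samples = 4L)
  dir <- tempfile("traj")
  on.exit(unlink(dir, recursive = TRUE))
  write_trajectory(tr, ds$vocab, dir)
  expect_true(file.exists(file.path(dir, "step_0.smi")))
  expect_true(file.exists(file.path(dir, "step_2.smi")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$K, 2L)
  expect_identical(man$snapshots$`0`$total, 4L)
  # step-0 training inits are all valid molecules
  expect_identical(man$snapshots$`0`$valid, 4L)
})
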