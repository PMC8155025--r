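# Distribution-learning metrics: hand-countable ratios, KLD score behavior,
# the Frechet hook, and the Spearman correlation analysis.

test_that("validity is the fraction passing parse-and-sanitize", {
  expect_identical(validity(c("C", "CC", "CCO")), 1)
  expect_equal(validity(c("C", "CC", "xyz")), 2 / 3, tolerance = 1e-12)
  expect_identical(validity(c("xyz", ")(")), 0)
  expect_error(validity(character(0)), "empty")
})

test_that("uniqueness deduplicates canonical forms of valid molecules", {
  expect_identical(uniqueness(c("C", "CC", "CCO")), 1)
  expect_equal(uniqueness(rep("C", 5)), 1 / 5, tolerance = 1e-12)
  expect_equal(uniqueness(c("CCO", "OCC")), 1 / 2, tolerance = 1e-12)
  # invalid entries are excluded from the denominator
  expect_equal(uniqueness(c("C", "C", "xyz")), 1 / 2, tolerance = 1e-12)
  expect_warning(u <- uniqueness(c("xyz", "abc")), "no valid")
  expect_identical(u, 0)
})

test_that("novelty counts distinct valid molecules outside the dataset", {
  dataset <- chem_canonicalize(c("C", "CC", "CCO"))
  expect_identical(novelty(c("C", "CC"), dataset), 0)
  expect_identical(novelty(c("CCN", "CCC"), dataset), 1)
  gen10 <- c("C", "CC", "CCO", "OCC", "CCN", "CCC", "CCCC", "CCCO", "C", "CC")
  # distinct valid canonical: C CC CCO CCN CCC CCCC CCCO -> 3 in, 4 out
  expect_equal(novelty(gen10, dataset), 4 / 7, tolerance = 1e-12)
  # duplicate spam cannot inflate the score
  expect_equal(novelty(c("CCN", rep("C", 50)), dataset), 1 / 2, tolerance = 1e-12)
})

test_that("kld_score is 1 on identical samples and orders degenerate sets", {
  smi <- fixture3()
  suppressWarnings({
    s_same <- kld_score(smi, smi)
    s_rep <- kld_score(rep("C", length(smi)), smi)
  })
  expect_equal(s_same, 1, tolerance = 1e-6)
  expect_lt(s_rep, s_same)
})

test_that("per-descriptor KL responds monotonically to a location shift", {
  set.seed(3)
  ref <- rnorm(2000)
  kls <- vapply(c(0, 0.5, 1, 2), function(shift)
    maskmol:::.descr_kl(ref, ref + shift), numeric(1))
  expect_identical(kls[1], 0)
  expect_true(all(diff(kls) > 0))
  # degenerate distributions fall back to smoothed histograms, finite KL
  expect_true(is.finite(maskmol:::.descr_kl(rep(1, 50), rnorm(50))))
})

test_that("frechet hook: explicit no-embedder status and closed forms", {
  out <- frechet_hook(c("C"), c("CC"))
  expect_identical(out$status, "not computed")
  expect_true(is.na(out$score))

  # identical samples -> distance 0, maximal score
  emb <- function(smiles) matrix(seq_along(smiles), ncol = 1)
  same <- frechet_hook(c("C", "CC", "CCO"), c("C", "CC", "CCO"), emb)
  expect_equal(same$distance, 0, tolerance = 1e-12)
  expect_equal(same$score, 1, tolerance = 1e-12)

  # 1-D Gaussian closed form: d = (m1-m2)^2 + (s1-s2)^2
  e1 <- c(1, 2, 3, 4); e2 <- c(10, 12, 14, 16)
  fh <- frechet_hook(letters[1:4], letters[1:4],
                     local({ i <- 0; function(s) {
                       i <<- i + 1; matrix(if (i == 1) e1 else e2, ncol = 1) } }))
  d_exp <- (mean(e1) - mean(e2))^2 + (sd(e1) - sd(e2))^2
  expect_equal(fh$distance, d_exp, tolerance = 1e-10)

  # equal covariances -> distance equals the squared mean shift
  set.seed(8)
  base <- matrix(rnorm(300), ncol = 3)
  sh <- frechet_hook(letters[1:4], letters[1:4],
                     local({ i <- 0; function(s) {
                       i <<- i + 1; if (i == 1) base else base + 2 } }))
  expect_equal(sh$distance, sum(rep(2, 3)^2), tolerance = 1e-8)
})

test_that("spearman matrix matches a brute-force rank oracle", {
  runs <- cbind(validity = c(0.9, 0.7, 0.8, 0.6, 0.95),
                uniqueness = c(0.5, 0.52, 0.47, 0.60, 0.55),
                novelty = c(0.2, 0.6, 0.4, 0.8, 0.1),
                kld = c(0.95, 0.70, 0.85, 0.55, 0.97),
                frechet = c(0.90, 0.60, 0.80, 0.50, 0.92))
  cm <- spearman_matrix(runs)
  expect_true(all(diag(cm) == 1))
  expect_equal(cm, t(cm), tolerance = 1e-12)
  # brute force: rank (average ties) then Pearson
  oracle <- stats::cor(apply(runs, 2, rank))
  expect_equal(unclass(cm), unclass(oracle), tolerance = 1e-12)
  # anti-monotone pair
  expect_equal(cm["validity", "novelty"], -1, tolerance = 1e-12)

  runs_const <- cbind(runs, constant = rep(0.5, 5))
  expect_warning(cmc <- spearman_matrix(runs_const), "constant")
  expect_true(all(is.na(cmc["constant", setdiff(colnames(runs_const), "constant")])))
  expect_identical(cmc["constant", "constant"], 1)
  expect_error(spearman_matrix(runs[1:2, ]), "at least 3")
})

test_that("metric reports aggregate the scores with provenance", {
  ds <- structure(list(smiles = fixture3(), canonical_set = fixture3()),
                  class = "mgm_dataset")
  gen <- c(fixture3()[1:5], "CCCCC", "xyz")
  suppressWarnings(rep <- metric_report(gen, ds,
                                        provenance = list(alpha = 0.1, K = 10),
                                        include_similarity = FALSE))
  expect_equal(rep$validity, 6 / 7, tolerance = 1e-12)
  expect_equal(rep$novelty, 1 / 6, tolerance = 1e-12)
  expect_true(rep$kld_score >= 0 && rep$kld_score <= 1)
  expect_identical(rep$n_evaluated, 7L)
  expect_null(rep$frechet_score)
  json <- tempfile(fileext = ".json"); csv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(json, csv)))
  write_metric_report(rep, json = json, csv = csv)
  expect_identical(jsonlite::read_json(json)$provenance$alpha, 0.1)
  expect_equal(utils::read.csv(csv)$validity, 6 / 7, tolerance = 1e-10)
})
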