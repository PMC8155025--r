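# GuacaMol-style distribution-learning metrics.  Conventions follow the
# GuacaMol implementation: uniqueness and novelty are computed on canonical
# forms of the *valid* molecules only, novelty against the combined dataset
# canonical set; the KL-divergence score averages exp(-KL) over a fixed
# physiochemical descriptor panel plus internal pairwise similarity.

#' Validity: fraction of SMILES that parse and sanitize
#' @param smiles_list character vector of generated SMILES.
#' @return ratio in `[0, 1]`.
#' @export
validity <- function(smiles_list) {
  if (length(smiles_list) == 0) stop("validity: empty list", call. = FALSE)
  mean(!is.na(chem_canonicalize(smiles_list)))
}

#' Uniqueness: distinct canonical forms among valid molecules
#' @param smiles_list character vector of generated SMILES.
#' @return ratio; 0 with a warning when no molecule is valid.
#' @export
uniqueness <- function(smiles_list) {
  if (length(smiles_list) == 0) stop("uniqueness: empty list", call. = FALSE)
  canon <- chem_canonicalize(smiles_list)
  canon <- canon[!is.na(canon)]
  if (length(canon) == 0) {
    warning("uniqueness: no valid molecules; reporting 0")
    return(0)
  }
  length(unique(canon)) / length(canon)
}

#' Novelty: distinct valid canonical molecules absent from the dataset
#'
#' The dataset set should contain canonical forms of the combined splits (the
#' "dataset distribution": train + valid (+ test)).  Deduplication happens
#' before the membership test, so duplicate spam cannot inflate the score.
#'
#' @param smiles_list character vector of generated SMILES.
#' @param dataset_canonical_set character vector of canonical dataset SMILES.
#' @return ratio; 0 with a warning when no molecule is valid.
#' @export
novelty <- function(smiles_list, dataset_canonical_set) {
  if (length(smiles_list) == 0 || length(dataset_canonical_set) == 0) {
    stop("novelty: empty input", call. = FALSE)
  }
  canon <- unique(chem_canonicalize(smiles_list))
  canon <- canon[!is.na(canon)]
  if (length(canon) == 0) {
    warning("novelty: no valid molecules; reporting 0")
    return(0)
  }
  mean(!(canon %in% dataset_canonical_set))
}

# KL(p || q) between two empirical samples of one descriptor.
# Continuous: kernel density estimates evaluated on a shared grid.
# Discrete/degenerate: smoothed histograms over the combined support.
.descr_kl <- function(ref, gen, discrete = FALSE, eps = 1e-10) {
  ref <- ref[is.finite(ref)]; gen <- gen[is.finite(gen)]
  if (length(ref) < 2 || length(gen) < 2) return(NA_real_)
  if (!discrete && (stats::sd(ref) == 0 || stats::sd(gen) == 0)) discrete <- TRUE
  if (discrete) {
    support <- sort(unique(c(ref, gen)))
    p <- vapply(support, function(v) sum(ref == v), numeric(1)) + eps
    q <- vapply(support, function(v) sum(gen == v), numeric(1)) + eps
    p <- p / sum(p); q <- q / sum(q)
    return(sum(p * log(p / q)))
  }
  lo <- min(ref, gen); hi <- max(ref, gen)
  pad <- 0.1 * (hi - lo)
  grid <- seq(lo - pad, hi + pad, length.out = 512)
  dp <- stats::density(ref, from = grid[1], to = grid[512], n = 512)$y + eps
  dq <- stats::density(gen, from = grid[1], to = grid[512], n = 512)$y + eps
  p <- dp / sum(dp); q <- dq / sum(dq)
  sum(p * log(p / q))
}

.KLD_DISCRETE <- c("NumHAcceptors", "NumHDonors", "NumRotatableBonds",
                   "NumAliphaticRings", "NumAromaticRings")

#' KL-divergence score between generated and dataset molecules
#'
#' Computes the benchmark descriptor panel (BertzCT, MolLogP, MolWt, TPSA,
#' H-bond acceptor/donor counts, rotatable bonds, aliphatic/aromatic ring
#' counts, internal pairwise Tanimoto similarity) on the valid molecules of
#' both sides, estimates each distribution (KDE for continuous descriptors,
#' smoothed histograms for counts), and averages `exp(-KL(dataset ||
#' generated))` across descriptors.  1 means distributionally
#' indistinguishable.
#'
#' @param generated_smiles,dataset_smiles character vectors of SMILES.
#' @param include_similarity include the internal-similarity descriptor
#'   (extra fingerprint work; default TRUE).
#' @return score in `[0, 1]`.
#' @export
kld_score <- function(generated_smiles, dataset_smiles, include_similarity = TRUE) {
  gen <- chem_canonicalize(generated_smiles)
  gen <- generated_smiles[!is.na(gen)]
  ref <- chem_canonicalize(dataset_smiles)
  ref <- dataset_smiles[!is.na(ref)]
  if (length(gen) < 2 || length(ref) < 2) {
    stop("kld_score: need at least 2 valid molecules on each side", call. = FALSE)
  }
  if (length(gen) < 100 || length(ref) < 100) {
    warning("kld_score: fewer than 100 valid molecules on one side; estimate is noisy")
  }
  dg <- chem_descriptors(gen)
  dr <- chem_descriptors(ref)
  kls <- vapply(names(dr), function(nm)
    .descr_kl(dr[[nm]], dg[[nm]], discrete = nm %in% .KLD_DISCRETE), numeric(1))
  if (include_similarity) {
    simr <- chem_simmax(ref)
    simg <- chem_simmax(gen)
    if (sum(is.finite(simr)) >= 2 && sum(is.finite(simg)) >= 2) {
      kls <- c(kls, internal_similarity = .descr_kl(simr, simg))
    }
  }
  kls <- kls[is.finite(kls)]
  if (length(kls) == 0) stop("kld_score: no usable descriptor distributions",
                             call. = FALSE)
  mean(exp(-kls))
}

#' Frechet-distance hook over a pluggable molecule embedder
#'
#' The reference metric embeds molecules with a pretrained chemistry network
#' (ChemNet); those weights are external, so the embedder is an argument.
#' Gaussians are fit to both embedding clouds and the Frechet distance
#' `|mu1 - mu2|^2 + tr(S1 + S2 - 2 (S1 S2)^{1/2})` is mapped to a score by
#' `exp(-0.2 d)`.  Without an embedder the result is an explicit
#' "not computed" status, never a silent zero.
#'
#' @param generated_smiles,dataset_smiles character vectors of SMILES.
#' @param embedder function mapping a character vector of SMILES to a numeric
#'   matrix (one row per molecule), or `NULL`.
#' @return list with `status` ("ok"/"not computed"), `distance`, `score`.
#' @export
frechet_hook <- function(generated_smiles, dataset_smiles, embedder = NULL) {
  if (is.null(embedder)) {
    return(list(status = "not computed", distance = NA_real_, score = NA_real_))
  }
  e1 <- as.matrix(embedder(generated_smiles))
  e2 <- as.matrix(embedder(dataset_smiles))
  mu1 <- colMeans(e1); mu2 <- colMeans(e2)
  s1 <- stats::cov(e1); s2 <- stats::cov(e2)
  if (length(mu1) == 1) {
    covterm <- as.numeric(s1 + s2 - 2 * sqrt(s1 * s2))
  } else {
    eg <- eigen(s1, symmetric = TRUE)
    s1h <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
    mid <- s1h %*% s2 %*% s1h
    ev <- eigen((mid + t(mid)) / 2, symmetric = TRUE, only.values = TRUE)$values
    covterm <- sum(diag(s1)) + sum(diag(s2)) - 2 * sum(sqrt(pmax(ev, 0)))
  }
  d <- sum((mu1 - mu2)^2) + covterm
  list(status = "ok", distance = d, score = exp(-0.2 * d))
}

#' Spearman rank-correlation matrix across generation runs
#'
#' @param runs matrix or data.frame: one row per generation setting, one
#'   column per metric (>= 3 rows required).  Ties get average ranks.
#' @return symmetric correlation matrix with unit diagonal; a constant
#'   column yields `NA` entries (undefined) with a warning.
#' @export
spearman_matrix <- function(runs) {
  runs <- as.matrix(runs)
  if (nrow(runs) < 3) stop("spearman_matrix: need at least 3 runs", call. = FALSE)
  const <- apply(runs, 2, function(x) stats::sd(x) == 0)
  cm <- suppressWarnings(stats::cor(runs, method = "spearman"))
  if (any(const)) {
    warning(sprintf("spearman_matrix: constant column(s) %s; correlations undefined",
                    paste(colnames(runs)[const], collapse = ", ")))
    cm[const, ] <- NA_real_
    cm[, const] <- NA_real_
  }
  diag(cm) <- 1
  cm
}

#' Full distribution-learning metric report for a generated set
#'
#' @param generated_smiles character vector of generated SMILES.
#' @param dataset an `mgm_dataset` providing the canonical set and reference
#'   SMILES.
#' @param provenance optional list of generation settings (alpha, K, init,
#'   seed) copied into the report.
#' @param embedder optional Frechet embedder (see [frechet_hook()]).
#' @param include_similarity forwarded to [kld_score()].
#' @return an `mgm_metric_report` list.
#' @export
metric_report <- function(generated_smiles, dataset, provenance = list(),
                          embedder = NULL, include_similarity = TRUE) {
  rep <- list(
    validity = validity(generated_smiles),
    uniqueness = uniqueness(generated_smiles),
    novelty = novelty(generated_smiles, dataset$canonical_set),
    kld_score = kld_score(generated_smiles, dataset$smiles,
                          include_similarity = include_similarity),
    n_evaluated = length(generated_smiles),
    provenance = provenance
  )
  fr <- frechet_hook(generated_smiles, dataset$smiles, embedder)
  if (identical(fr$status, "ok")) rep$frechet_score <- fr$score
  structure(rep, class = "mgm_metric_report")
}

#' @export
print.mgm_metric_report <- function(x, ...) {
  cat(sprintf(paste0("<mgm_metric_report: validity %.3f, uniqueness %.3f, ",
                     "novelty %.3f, KLD %.3f%s (n=%d)>\n"),
              x$validity, x$uniqueness, x$novelty, x$kld_score,
              if (!is.null(x$frechet_score)) sprintf(", Frechet %.3f", x$frechet_score)
              else "", x$n_evaluated))
  invisible(x)
}

#' Write a metric report as JSON and/or CSV
#' @param report an `mgm_metric_report`.
#' @param json,csv optional output paths.
#' @export
write_metric_report <- function(report, json = NULL, csv = NULL) {
  if (!is.null(json)) {
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  if (!is.null(csv)) {
    flat <- report[c("validity", "uniqueness", "novelty", "kld_score")]
    if (!is.null(report$frechet_score)) flat$frechet_score <- report$frechet_score
    utils::write.csv(as.data.frame(flat), csv, row.names = FALSE)
  }
  invisible(report)
}
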