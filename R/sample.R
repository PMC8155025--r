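# Generation: Gibbs-style iterative masked resampling.  A chain starts from a
# training graph or from per-slot training marginals, then repeats K times:
# draw ceiling(alpha*S) of the S slots without replacement, mask them, run the
# network once, and resample every masked slot from its predicted categorical.
# Many chains run in parallel, batched by node count, exactly like the
# reference setting's batched generation.

#' Empirical per-slot marginals of a training set
#'
#' @param dataset an `mgm_dataset`.
#' @return an `mgm_marginals` object: per node property a frequency vector
#'   over its real categories, an edge-type frequency vector over all
#'   prospective edges, and the empirical node-count distribution.
#' @export
estimate_marginals <- function(dataset) {
  if (length(dataset$graphs) == 0) stop("estimate_marginals: empty dataset",
                                        call. = FALSE)
  vocab <- dataset$vocab
  stopifnot(!is.null(vocab))
  nodes_all <- do.call(rbind, lapply(dataset$graphs, `[[`, "nodes"))
  node <- lapply(1:6, function(k) {
    tk <- vocab_n_categories(vocab, k)
    tabulate(nodes_all[, k], nbins = tk) / nrow(nodes_all)
  })
  names(node) <- MGM_NODE_PROPS
  edges_all <- unlist(lapply(dataset$graphs, `[[`, "edges"), use.names = FALSE)
  edge <- if (length(edges_all) > 0) {
    tabulate(edges_all, nbins = length(MGM_EDGE_TYPES)) / length(edges_all)
  } else {
    stats::setNames(c(1, 0, 0, 0, 0), MGM_EDGE_TYPES)  # degenerate: single-atom set
  }
  ncounts <- table(vapply(dataset$graphs, `[[`, integer(1), "n"))
  structure(list(node = node, edge = as.numeric(edge),
                 node_count = list(values = as.integer(names(ncounts)),
                                   probs = as.numeric(ncounts) / sum(ncounts))),
            class = "mgm_marginals")
}

#' Initialize a generation chain
#'
#' `"training"` draws a uniform random graph from the training data;
#' `"marginal"` draws the node count from its empirical distribution, then
#' fills every node-property slot and edge slot i.i.d. from its marginal
#' (such graphs typically contain several disjoint fragments).
#'
#' @param strategy `"training"` or `"marginal"`.
#' @param source an `mgm_dataset` (training strategy) or `mgm_marginals`.
#' @param seed optional RNG seed.
#' @return an `mgm_graph` with no MASK indices.
#' @export
init_graph <- function(strategy = c("training", "marginal"), source, seed = NULL) {
  strategy <- match.arg(strategy)
  with_seed_opt(seed, {
    if (strategy == "training") {
      stopifnot(inherits(source, "mgm_dataset"))
      g <- source$graphs[[sample.int(length(source$graphs), 1L)]]
      g$y <- NULL
      g
    } else {
      stopifnot(inherits(source, "mgm_marginals"))
      nc <- source$node_count
      n <- nc$values[sample.int(length(nc$values), 1L, prob = nc$probs)]
      nodes <- vapply(1:6, function(k)
        sample.int(length(source$node[[k]]), n, replace = TRUE,
                   prob = source$node[[k]]), integer(n))
      if (n == 1L) nodes <- matrix(nodes, 1L, 6L)
      colnames(nodes) <- MGM_NODE_PROPS
      P <- (n * (n - 1L)) %/% 2L
      edges <- if (P > 0) sample.int(5L, P, replace = TRUE, prob = source$edge)
               else integer(0)
      new_graph(nodes, edges)
    }
  })
}

#' Sampler configuration
#'
#' @param init initialization strategy, `"training"` or `"marginal"`.
#' @param alpha generation masking rate: the fraction of pooled slots
#'   resampled per step (ceiling-rounded count, so any `alpha > 0` moves at
#'   least one slot).
#' @param K number of sampling iterations.
#' @param record_every integer vector of iteration indices (0 = the
#'   initialization) at which snapshots are kept; `NULL` keeps all `K + 1`.
#' @param y_target optional conditional target property value (raw scale).
#' @param temperature softmax temperature for resampling (1 = the model's
#'   distribution; kept as an option, defaults off).
#' @param seed RNG seed fixing the entire trajectory.
#' @return an object of class `mgm_sampler_config`.
#' @export
sampler_config <- function(init = c("training", "marginal"), alpha = 0.1,
                           K = 400L, record_every = NULL, y_target = NULL,
                           temperature = 1, seed = NULL) {
  init <- match.arg(init)
  stopifnot(K >= 0, alpha >= 0, alpha <= 1, temperature > 0)
  if (K > 0 && alpha <= 0) {
    warning("sampler_config: alpha = 0 with K > 0; every step is an identity step")
  }
  structure(list(init = init, alpha = alpha, K = as.integer(K),
                 record_every = record_every, y_target = y_target,
                 temperature = temperature, seed = seed),
            class = "mgm_sampler_config")
}

# Vectorized categorical sampling: one draw per row of a logits matrix.
sample_rows <- function(logits, temperature = 1) {
  pr <- row_softmax(logits / temperature)
  cs <- pr %*% upper.tri(diag(ncol(pr)), diag = TRUE)  # row-wise cumsum
  u <- stats::runif(nrow(pr))
  # keep integer storage: a double write would coerce the graph matrices
  pmin(as.integer(rowSums(cs < u)) + 1L, ncol(pr))
}

# Resample all masked slots of a same-size batch in one forward pass.
# Consumes the ambient RNG stream; graphs come back MASK-free.
step_batch <- function(params, graphs, alpha, y_std = NULL, temperature = 1) {
  vocab <- params$vocab
  n <- graphs[[1]]$n
  masked <- lapply(graphs, mask_graph_fixed, alpha = alpha, vocab = vocab)
  corrupted <- lapply(masked, `[[`, "graph")
  masks <- lapply(masked, `[[`, "mask")
  batch <- build_batch(corrupted, vocab)
  fw <- forward_batch(params, batch, y_std = y_std)
  P <- (n * (n - 1L)) %/% 2L
  out <- graphs
  for (k in 1:6) {
    rows <- integer(0); whichb <- integer(0); whichi <- integer(0)
    for (b in seq_along(masks)) {
      mk <- masks[[b]]$nodes
      sel <- which(mk[, 2] == k)
      if (length(sel) > 0) {
        ii <- mk[sel, 1]
        rows <- c(rows, (b - 1L) * n + ii)
        whichb <- c(whichb, rep(b, length(ii)))
        whichi <- c(whichi, ii)
      }
    }
    if (length(rows) == 0) next
    cls <- sample_rows(fw$node_logits[[k]][rows, , drop = FALSE], temperature)
    for (t in seq_along(rows)) out[[whichb[t]]]$nodes[whichi[t], k] <- cls[t]
  }
  erows <- integer(0); ewb <- integer(0); ewe <- integer(0)
  for (b in seq_along(masks)) {
    ee <- masks[[b]]$edges
    if (length(ee) > 0) {
      erows <- c(erows, (b - 1L) * P + ee)
      ewb <- c(ewb, rep(b, length(ee)))
      ewe <- c(ewe, ee)
    }
  }
  if (length(erows) > 0) {
    cls <- sample_rows(fw$edge_logits[erows, , drop = FALSE], temperature)
    for (t in seq_along(erows)) out[[ewb[t]]]$edges[ewe[t]] <- cls[t]
  }
  out
}

#' One masked-resampling generation step
#'
#' Masks `ceiling(alpha * S)` of the graph's `S` pooled slots, predicts their
#' conditional distributions in a single forward pass (the masked slots are
#' conditionally independent given the rest), samples new values, and writes
#' them back.  At most the masked slots can change.
#'
#' @param graph an `mgm_graph` with no MASK indices.
#' @param params an `mgm_params`.
#' @param alpha generation masking rate.
#' @param y optional raw conditional target (required iff the model is
#'   conditional).
#' @param temperature softmax temperature (default 1).
#' @param seed optional RNG seed.
#' @return the updated `mgm_graph` (no MASK indices).
#' @export
generate_step <- function(graph, params, alpha, y = NULL, temperature = 1,
                          seed = NULL) {
  if (alpha == 0) {
    warning("generate_step: alpha = 0 is an identity step")
    return(graph)
  }
  y_std <- NULL
  if (params$config$conditional) {
    if (is.null(y)) stop("generate_step: conditional model requires y", call. = FALSE)
    y_std <- standardize_property(y, params$meta$y_mean, params$meta$y_sd)
  }
  with_seed_opt(seed,
    step_batch(params, list(graph), alpha, y_std = y_std,
               temperature = temperature)[[1]])
}

#' Generate molecules by iterative masked resampling
#'
#' Runs `n_samples` chains for `K` steps each; chains are batched by node
#' count so each step costs a handful of forward passes regardless of the
#' number of chains.  The trajectory includes the initialization as step 0.
#'
#' @param params a trained `mgm_params`.
#' @param config an `mgm_sampler_config`.
#' @param source an `mgm_dataset` (training init) or `mgm_marginals`
#'   (marginal init).
#' @param n_samples number of chains.
#' @return an `mgm_trajectory`: `snapshots` (named list, step index as name,
#'   each a list of `mgm_graph`), `final` (graphs after step `K`), and
#'   `manifest` (generation settings provenance).
#' @export
generate <- function(params, config, source, n_samples = 1L) {
  y_std <- NULL
  if (params$config$conditional) {
    if (is.null(config$y_target)) {
      stop("generate: conditional model requires config$y_target", call. = FALSE)
    }
    y_std <- standardize_property(config$y_target, params$meta$y_mean,
                                  params$meta$y_sd)
  }
  rec <- config$record_every %||% (0:config$K)
  snapshots <- list()
  with_seed_opt(config$seed, {
    graphs <- lapply(seq_len(n_samples), function(i) init_graph(config$init, source))
    if (0L %in% rec) snapshots[["0"]] <- graphs
    if (config$K > 0 && config$alpha > 0) {
      sizes <- vapply(graphs, `[[`, integer(1), "n")
      groups <- split(seq_len(n_samples), sizes)
      for (step in seq_len(config$K)) {
        for (grp in groups) {
          yb <- if (!is.null(y_std)) rep(y_std, length(grp)) else NULL
          graphs[grp] <- step_batch(params, graphs[grp], config$alpha,
                                    y_std = yb, temperature = config$temperature)
        }
        if (step %in% rec) snapshots[[as.character(step)]] <- graphs
      }
    } else if (config$K > 0) {
      for (step in seq_len(config$K)) {
        if (step %in% rec) snapshots[[as.character(step)]] <- graphs
      }
    }
  })
  structure(list(
    snapshots = snapshots, final = graphs,
    manifest = list(init = config$init, alpha = config$alpha, K = config$K,
                    n_samples = n_samples, y_target = config$y_target,
                    temperature = config$temperature, seed = config$seed)),
    class = "mgm_trajectory")
}

#' @export
print.mgm_trajectory <- function(x, ...) {
  cat(sprintf("<mgm_trajectory: %d chains, K=%d, %d snapshots (%s init, alpha=%.3g)>\n",
              x$manifest$n_samples, x$manifest$K, length(x$snapshots),
              x$manifest$init, x$manifest$alpha))
  invisible(x)
}

#' Serialize trajectory snapshots as SMILES files plus a JSON manifest
#'
#' One `step_<k>.smi` per recorded snapshot (invalid graphs appear as empty
#' lines are omitted and counted in the manifest), plus `manifest.json`.
#'
#' @param trajectory an `mgm_trajectory`.
#' @param vocab the model vocabulary.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(trajectory, vocab, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  for (step in names(trajectory$snapshots)) {
    smi <- graphs_to_smiles(trajectory$snapshots[[step]], vocab)
    writeLines(smi[!is.na(smi)], file.path(dir, sprintf("step_%s.smi", step)))
    counts[[step]] <- list(total = length(smi), valid = sum(!is.na(smi)))
  }
  manifest <- c(trajectory$manifest, list(snapshots = counts))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
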