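# The corruption process C(G_\eta | G): replace randomly chosen node-property
# and prospective-edge slots by their MASK index.  Two draw schemes coexist on
# purpose:
#   * training/validation: Bernoulli per slot at rate alpha ("with probability
#     alpha"), independently for every property on every component;
#   * generation: a fixed-count draw of ceiling(alpha * S) slots without
#     replacement from the pooled S = 6N + N(N-1)/2 slots ("a fraction alpha
#     of components"), so a generation step with alpha > 0 always resamples
#     at least one slot.

#' Masking configuration
#'
#' @param training_rate_range interval from which the per-graph training rate
#'   is drawn uniformly (default `c(0, 0.2)`).
#' @param validation_rate fixed rate used for validation loss (default 0.1).
#' @param seed optional RNG seed attached to the config.
#' @return an object of class `mgm_mask_config`.
#' @export
mask_config <- function(training_rate_range = c(0, 0.2), validation_rate = 0.1,
                        seed = NULL) {
  r <- training_rate_range
  if (length(r) != 2 || r[1] > r[2]) {
    stop("mask_config: degenerate training_rate_range (min > max)", call. = FALSE)
  }
  if (r[1] < 0 || r[2] > 1 || validation_rate < 0 || validation_rate > 1) {
    stop("mask_config: rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(training_rate_range = as.numeric(r),
                 validation_rate = as.numeric(validation_rate), seed = seed),
            class = "mgm_mask_config")
}

#' Draw a training masking rate
#'
#' Uniform over the configured training range; one draw per graph per step.
#'
#' @param config an `mgm_mask_config`.
#' @param seed optional seed overriding the config's.
#' @return numeric scalar alpha.
#' @export
sample_training_rate <- function(config, seed = NULL) {
  r <- config$training_rate_range
  with_seed_opt(seed %||% config$seed, stats::runif(1, r[1], r[2]))
}

# Total number of maskable slots of an N-node graph.
n_slots <- function(n) 6L * n + (n * (n - 1L)) %/% 2L

#' Corrupt a graph by independent Bernoulli masking
#'
#' Each of the `6N` node-property slots and each of the `N(N-1)/2`
#' prospective-edge slots is replaced by its MASK index independently with
#' probability `alpha`.  The choice for one property is independent of every
#' other property on the same component.
#'
#' @param graph an `mgm_graph` with no MASK indices.
#' @param alpha masking probability in `[0, 1]`.
#' @param vocab the matching `mgm_vocab`.
#' @param seed optional RNG seed (deterministic corruption when fixed).
#' @return list with `graph` (corrupted copy) and `mask`, an `mgm_mask_set`
#'   with `nodes` (two-column matrix: node index, property index) and `edges`
#'   (pair-slot indices) recording exactly the replaced slots.
#' @export
mask_graph <- function(graph, alpha, vocab, seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (graph_has_mask(graph, vocab)) {
    stop("mask_graph: input already contains MASK indices", call. = FALSE)
  }
  with_seed_opt(seed, {
    n <- graph$n
    node_hits <- matrix(stats::runif(n * 6L) < alpha, n, 6L)
    edge_hits <- stats::runif(length(graph$edges)) < alpha
    .apply_mask(graph, vocab, which(node_hits, arr.ind = TRUE), which(edge_hits))
  })
}

#' Corrupt a graph by a fixed-count pooled draw (generation scheme)
#'
#' Draws `ceiling(alpha * S)` of the `S = 6N + N(N-1)/2` slots uniformly
#' without replacement, pooled over node-property and edge slots, and masks
#' them.  Ceiling rounding guarantees at least one slot whenever `alpha > 0`.
#'
#' @inheritParams mask_graph
#' @export
mask_graph_fixed <- function(graph, alpha, vocab, seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (graph_has_mask(graph, vocab)) {
    stop("mask_graph_fixed: input already contains MASK indices", call. = FALSE)
  }
  with_seed_opt(seed, {
    n <- graph$n
    s_tot <- n_slots(n)
    k <- ceiling(alpha * s_tot)
    slots <- if (k > 0) sample.int(s_tot, k) else integer(0)
    node_slots <- slots[slots <= 6L * n]
    edge_slots <- slots[slots > 6L * n] - 6L * n
    # node slot s encodes (node i, property kappa) as s = (kappa-1)*N + i
    nodes_hit <- cbind(row = ((node_slots - 1L) %% n) + 1L,
                       col = ((node_slots - 1L) %/% n) + 1L)
    .apply_mask(graph, vocab, nodes_hit, edge_slots)
  })
}

.apply_mask <- function(graph, vocab, nodes_hit, edge_slots) {
  corrupted <- graph
  if (nrow(nodes_hit) > 0) {
    masks <- vapply(vocab$node, `[[`, integer(1), "mask_index")
    corrupted$nodes[nodes_hit] <- masks[nodes_hit[, 2]]
  }
  if (length(edge_slots) > 0) {
    corrupted$edges[edge_slots] <- vocab$edge$mask_index
  }
  mask <- structure(list(nodes = unname(nodes_hit), edges = as.integer(edge_slots)),
                    class = "mgm_mask_set")
  list(graph = corrupted, mask = mask)
}

n_masked_slots <- function(mask) nrow(mask$nodes) + length(mask$edges)
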