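# Batched forward pass.  Graphs with the same node count N are stacked into
# one "batch": node states are rows of a (B*N) x d0 matrix (graph-major), edge
# states rows of a (B*P) x d0 matrix with P = N(N-1)/2 pair slots, edge row
# r = (g-1)*P + p.  Two nodes are MPNN neighbors iff their pair slot is
# masked or has a bond (type other than "none"); the neighborhood is read
# once from the corrupted input graph and stays fixed across layers.
# Gathers/scatters are vectorized over all B*P pair slots (rowsum), which is
# what keeps long sampling chains affordable in R.

# ---- batch construction ----------------------------------------------------

build_batch <- function(graphs, vocab) {
  n <- graphs[[1]]$n
  stopifnot(all(vapply(graphs, `[[`, integer(1), "n") == n))
  B <- length(graphs)
  P <- (n * (n - 1L)) %/% 2L
  node_idx <- do.call(rbind, lapply(graphs, `[[`, "nodes"))
  edge_idx <- unlist(lapply(graphs, `[[`, "edges"), use.names = FALSE)
  if (is.null(edge_idx)) edge_idx <- integer(0)
  pairs <- graph_pairs(n)
  # edge-row-aligned node row indices: row r = (g-1)*P + p maps to nodes
  # (g-1)*n + i_p and (g-1)*n + j_p
  off_n <- rep((seq_len(B) - 1L) * n, each = P)
  gi <- off_n + rep(pairs[, 1L], times = B)
  gj <- off_n + rep(pairs[, 2L], times = B)
  active <- edge_idx != 1L  # masked (MASK index) or bonded; "none" == 1
  list(n = n, B = B, P = P, node_idx = node_idx, edge_idx = edge_idx,
       pairs = pairs, gi = gi, gj = gj, active = active)
}

addv <- function(M, v) M + rep(v, each = nrow(M))  # add row vector
mulv <- function(M, v) M * rep(v, each = nrow(M))  # scale columns

relu <- function(x) (x > 0) * x
sigm <- function(x) 1 / (1 + exp(-x))

# scatter-add `msg` rows into an (nrow_out x d) matrix by target row `tgt`
scatter_rows <- function(msg, tgt, nrow_out) {
  rs <- rowsum(msg, group = tgt)
  out <- matrix(0, nrow_out, ncol(msg))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# ---- forward core ----------------------------------------------------------

# y_std: standardized conditioning scalar, length B (or NULL).
forward_batch <- function(params, batch, y_std = NULL, want_cache = FALSE) {
  par <- params$par
  cfg <- params$config
  d0 <- cfg$d0
  B <- batch$B; n <- batch$n; P <- batch$P
  gi <- batch$gi; gj <- batch$gj

  hv <- par$emb_node_1[batch$node_idx[, 1L], , drop = FALSE]
  for (k in 2:6) {
    hv <- hv + par[[paste0("emb_node_", k)]][batch$node_idx[, k], , drop = FALSE]
  }
  cond_cache <- NULL
  if (cfg$conditional) {
    if (is.null(y_std)) stop("forward: conditional model requires y_std", call. = FALSE)
    ymat <- matrix(as.numeric(y_std), nrow = B, ncol = 1L)
    c_pre <- addv(ymat %*% par$cond_W1, par$cond_b1)
    c_h <- relu(c_pre)
    c_out <- addv(c_h %*% par$cond_W2, par$cond_b2)
    hv <- hv + c_out[rep(seq_len(B), each = n), , drop = FALSE]
    cond_cache <- list(ymat = ymat, c_pre = c_pre, c_h = c_h)
  }
  he <- if (P > 0) par$emb_edge[batch$edge_idx, , drop = FALSE] else matrix(0, 0, d0)

  act <- as.numeric(batch$active)
  layers <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    hv_in <- hv; he_in <- he
    # aggregation: u_i = sum_{j in N(i)} h_e(ij) . h_vj  +  sum h_vj
    if (P > 0) {
      hvi <- hv_in[gi, , drop = FALSE]
      hvj <- hv_in[gj, , drop = FALSE]
      if (cfg$product == "hadamard") {
        mij <- (he_in * hvj + hvj) * act
        mji <- (he_in * hvi + hvi) * act
      } else {  # scaled inner product reweights the neighbor state
        cij <- rowSums(he_in * hvj) / d0
        cji <- rowSums(he_in * hvi) / d0
        mij <- (cij + 1) * hvj * act
        mji <- (cji + 1) * hvi * act
      }
      u <- scatter_rows(rbind(mij, mji), c(gi, gj), B * n)
    } else {
      u <- matrix(0, B * n, d0)
    }
    # GRU(h = previous node state, input = accumulated message)
    r <- sigm(addv(u %*% par$gru_Wr + hv_in %*% par$gru_Ur, par$gru_br))
    z <- sigm(addv(u %*% par$gru_Wz + hv_in %*% par$gru_Uz, par$gru_bz))
    q <- addv(hv_in %*% par$gru_Un, par$gru_bn2)
    nn <- tanh(addv(u %*% par$gru_Wn, par$gru_bn1) + r * q)
    gru_out <- (1 - z) * nn + z * hv_in
    # LayerNorm over the feature dimension
    mu <- rowMeans(gru_out)
    xc <- gru_out - mu
    inv <- 1 / sqrt(rowMeans(xc^2) + 1e-5)
    xhat <- xc * inv
    hv <- addv(mulv(xhat, par$ln_g), par$ln_b)
    # edge update from pre-update node states, active pairs only
    if (P > 0) {
      s <- hv_in[gi, , drop = FALSE] + hv_in[gj, , drop = FALSE]
      a1 <- addv(s %*% par$edge_E1, par$edge_b1)
      r1 <- relu(a1)
      he_new <- addv(r1 %*% par$edge_E2, par$edge_b2)
      he <- he_in
      he[batch$active, ] <- he_new[batch$active, , drop = FALSE]
    } else {
      s <- a1 <- r1 <- NULL
    }
    if (want_cache) {
      layers[[l]] <- list(hv_in = hv_in, he_in = he_in, u = u, r = r, z = z,
                          q = q, nn = nn, xhat = xhat, inv = inv,
                          s = s, a1 = a1, r1 = r1)
    }
  }

  # projection heads (top states only); outputs are logits over real categories
  node_logits <- vector("list", 6L)
  head_cache <- list(node = vector("list", 6L))
  for (k in 1:6) {
    w1 <- par[[paste0("head_n", k, "_W1")]]
    h1p <- addv(hv %*% w1, par[[paste0("head_n", k, "_b1")]])
    h1 <- relu(h1p)
    node_logits[[k]] <- addv(h1 %*% par[[paste0("head_n", k, "_W2")]],
                             par[[paste0("head_n", k, "_b2")]])
    if (want_cache) head_cache$node[[k]] <- list(pre = h1p, act = h1)
  }
  if (P > 0) {
    e1p <- addv(he %*% par$head_e_W1, par$head_e_b1)
    e1 <- relu(e1p)
    edge_logits <- addv(e1 %*% par$head_e_W2, par$head_e_b2)
    if (want_cache) head_cache$edge <- list(pre = e1p, act = e1)
  } else {
    edge_logits <- matrix(0, 0, length(params$vocab$edge$categories))
  }

  out <- list(node_logits = node_logits, edge_logits = edge_logits,
              hv_top = hv, he_top = he)
  if (want_cache) {
    out$cache <- list(layers = layers, heads = head_cache, cond = cond_cache,
                      y_std = y_std)
  }
  out
}

# ---- public single-graph forward -------------------------------------------

#' Forward pass: per-slot categorical distributions
#'
#' Embeds a (possibly corrupted) graph, applies `L` tied MPNN layers, and
#' projects every node-property slot and every prospective-edge slot onto the
#' probability simplex over its real categories (MASK is excluded from the
#' output simplex).
#'
#' @param graph an `mgm_graph`; MASK indices are allowed (and are the point).
#' @param params an `mgm_params`.
#' @param y optional raw conditioning property value; standardized internally
#'   with the training statistics stored in `params$meta`.
#' @return list with `node`: a list of 6 matrices (`n` rows each, one column
#'   per real category, rows summing to 1) and `edge`: a matrix with one row
#'   per pair slot over the 5 edge types.
#' @export
mgm_forward <- function(graph, params, y = NULL) {
  y_std <- NULL
  if (params$config$conditional) {
    if (is.null(y)) stop("mgm_forward: conditional model requires y", call. = FALSE)
    y_std <- standardize_property(y, params$meta$y_mean, params$meta$y_sd)
  }
  batch <- build_batch(list(graph), params$vocab)
  fw <- forward_batch(params, batch, y_std = y_std)
  probs_n <- lapply(fw$node_logits, row_softmax)
  probs_e <- if (nrow(fw$edge_logits) > 0) row_softmax(fw$edge_logits)
             else fw$edge_logits
  if (any(!is.finite(unlist(probs_n))) ||
      (length(probs_e) && any(!is.finite(probs_e)))) {
    stop("mgm_forward: non-finite values in output distributions", call. = FALSE)
  }
  list(node = probs_n, edge = probs_e)
}

#' MPNN neighborhood of a node
#'
#' `N(i)` contains every node `j != i` whose pair slot with `i` is masked or
#' carries a bond type other than `"none"`.
#'
#' @param graph an `mgm_graph` (typically corrupted).
#' @param i node index.
#' @return integer vector of neighbor indices.
#' @export
neighborhood <- function(graph, i) {
  stopifnot(i >= 1, i <= graph$n)
  if (graph$n < 2) return(integer(0))
  js <- setdiff(seq_len(graph$n), i)
  js[graph$edges[pair_index(i, js, graph$n)] != 1L]
}
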