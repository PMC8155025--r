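# Reverse-mode gradients for the batched forward pass, derived by hand and
# verified against central finite differences (test-gradients.R).  Layer
# parameters are tied, so per-layer contributions accumulate into one slot.
# Gathers/scatters mirror forward.R: edge-row-aligned index vectors gi/gj and
# rowsum-based scatter-adds.

# d_node_logits: list of 6 matrices, gradient of the scalar loss w.r.t. the
# node-head logits (rows of unmasked slots must be zero); d_edge_logits ditto
# for the edge head.  `fw` must come from forward_batch(want_cache = TRUE).
backward_batch <- function(params, batch, fw, d_node_logits, d_edge_logits) {
  par <- params$par
  cfg <- params$config
  d0 <- cfg$d0
  B <- batch$B; n <- batch$n; P <- batch$P
  gi <- batch$gi; gj <- batch$gj
  g <- par_zeros(par)
  act <- as.numeric(batch$active)

  # ---- heads ----
  dhv <- matrix(0, B * n, d0)
  for (k in 1:6) {
    dl <- d_node_logits[[k]]
    hc <- fw$cache$heads$node[[k]]
    w2 <- par[[paste0("head_n", k, "_W2")]]
    g[[paste0("head_n", k, "_W2")]] <- crossprod(hc$act, dl)
    g[[paste0("head_n", k, "_b2")]] <- colSums(dl)
    da <- (dl %*% t(w2)) * (hc$pre > 0)
    g[[paste0("head_n", k, "_W1")]] <- crossprod(fw$hv_top, da)
    g[[paste0("head_n", k, "_b1")]] <- colSums(da)
    dhv <- dhv + da %*% t(par[[paste0("head_n", k, "_W1")]])
  }
  dhe <- matrix(0, B * P, d0)
  if (P > 0 && !is.null(d_edge_logits)) {
    hc <- fw$cache$heads$edge
    g$head_e_W2 <- crossprod(hc$act, d_edge_logits)
    g$head_e_b2 <- colSums(d_edge_logits)
    da <- (d_edge_logits %*% t(par$head_e_W2)) * (hc$pre > 0)
    g$head_e_W1 <- crossprod(fw$he_top, da)
    g$head_e_b1 <- colSums(da)
    dhe <- da %*% t(par$head_e_W1)
  }

  # ---- tied MPNN layers, top down ----
  for (l in rev(seq_len(cfg$L))) {
    cc <- fw$cache$layers[[l]]
    dhv_in <- matrix(0, B * n, d0)

    # edge update path: active rows came from the MLP, inactive passed through
    dhe_next <- matrix(0, B * P, d0)
    if (P > 0) {
      dmlp <- dhe
      if (any(!batch$active)) dmlp[!batch$active, ] <- 0
      dhe_next[!batch$active, ] <- dhe[!batch$active, , drop = FALSE]
      g$edge_E2 <- g$edge_E2 + crossprod(cc$r1, dmlp)
      g$edge_b2 <- g$edge_b2 + colSums(dmlp)
      da1 <- (dmlp %*% t(par$edge_E2)) * (cc$a1 > 0)
      g$edge_E1 <- g$edge_E1 + crossprod(cc$s, da1)
      g$edge_b1 <- g$edge_b1 + colSums(da1)
      ds <- da1 %*% t(par$edge_E1)
      dhv_in <- dhv_in + scatter_rows(rbind(ds, ds), c(gi, gj), B * n)
    }

    # LayerNorm backward
    g$ln_g <- g$ln_g + colSums(dhv * cc$xhat)
    g$ln_b <- g$ln_b + colSums(dhv)
    dxhat <- mulv(dhv, par$ln_g)
    dx <- cc$inv * (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat))

    # GRU backward: out = (1-z)*nn + z*h
    dz <- dx * (cc$hv_in - cc$nn)
    dn <- dx * (1 - cc$z)
    dhv_in <- dhv_in + dx * cc$z
    dnpre <- dn * (1 - cc$nn^2)
    g$gru_Wn <- g$gru_Wn + crossprod(cc$u, dnpre)
    g$gru_bn1 <- g$gru_bn1 + colSums(dnpre)
    du <- dnpre %*% t(par$gru_Wn)
    dr <- dnpre * cc$q
    dq <- dnpre * cc$r
    g$gru_Un <- g$gru_Un + crossprod(cc$hv_in, dq)
    g$gru_bn2 <- g$gru_bn2 + colSums(dq)
    dhv_in <- dhv_in + dq %*% t(par$gru_Un)
    drpre <- dr * cc$r * (1 - cc$r)
    g$gru_Wr <- g$gru_Wr + crossprod(cc$u, drpre)
    g$gru_Ur <- g$gru_Ur + crossprod(cc$hv_in, drpre)
    g$gru_br <- g$gru_br + colSums(drpre)
    du <- du + drpre %*% t(par$gru_Wr)
    dhv_in <- dhv_in + drpre %*% t(par$gru_Ur)
    dzpre <- dz * cc$z * (1 - cc$z)
    g$gru_Wz <- g$gru_Wz + crossprod(cc$u, dzpre)
    g$gru_Uz <- g$gru_Uz + crossprod(cc$hv_in, dzpre)
    g$gru_bz <- g$gru_bz + colSums(dzpre)
    du <- du + dzpre %*% t(par$gru_Wz)
    dhv_in <- dhv_in + dzpre %*% t(par$gru_Uz)

    # aggregation backward
    if (P > 0) {
      hvi <- cc$hv_in[gi, , drop = FALSE]
      hvj <- cc$hv_in[gj, , drop = FALSE]
      dui <- du[gi, , drop = FALSE]
      duj <- du[gj, , drop = FALSE]
      if (cfg$product == "hadamard") {
        dhe_next <- dhe_next + act * (dui * hvj + duj * hvi)
        contrib_j <- act * dui * (cc$he_in + 1)  # into nodes gj
        contrib_i <- act * duj * (cc$he_in + 1)  # into nodes gi
      } else {
        cij <- rowSums(cc$he_in * hvj) / d0
        cji <- rowSums(cc$he_in * hvi) / d0
        dcij <- rowSums(dui * hvj) * act / d0
        dcji <- rowSums(duj * hvi) * act / d0
        dhe_next <- dhe_next + dcij * hvj + dcji * hvi
        contrib_j <- act * (cij + 1) * dui + dcij * cc$he_in
        contrib_i <- act * (cji + 1) * duj + dcji * cc$he_in
      }
      dhv_in <- dhv_in + scatter_rows(rbind(contrib_j, contrib_i),
                                      c(gj, gi), B * n)
    }
    dhv <- dhv_in
    dhe <- dhe_next
  }

  # ---- embeddings and conditioner ----
  for (k in 1:6) {
    rs <- rowsum(dhv, group = batch$node_idx[, k])
    nm <- paste0("emb_node_", k)
    rows <- as.integer(rownames(rs))
    g[[nm]][rows, ] <- g[[nm]][rows, , drop = FALSE] + rs
  }
  if (P > 0) {
    rs <- rowsum(dhe, group = batch$edge_idx)
    rows <- as.integer(rownames(rs))
    g$emb_edge[rows, ] <- g$emb_edge[rows, , drop = FALSE] + rs
  }
  if (cfg$conditional) {
    ccd <- fw$cache$cond
    dcond <- rowsum(dhv, group = rep(seq_len(B), each = n))
    g$cond_W2 <- crossprod(ccd$c_h, dcond)
    g$cond_b2 <- colSums(dcond)
    da <- (dcond %*% t(par$cond_W2)) * (ccd$c_pre > 0)
    g$cond_W1 <- crossprod(ccd$ymat, da)
    g$cond_b1 <- colSums(da)
  }
  g
}
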