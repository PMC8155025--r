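# Apply a node relabeling: node i of `g` becomes node perm[i].
relabel_graph <- function(g, perm) {
  out <- g
  out$nodes[perm, ] <- g$nodes
  pr <- graph_pairs(g$n)
  out$edges[pair_index(perm[pr[, 1]], perm[pr[, 2]], g$n)] <- g$edges
  out
}
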