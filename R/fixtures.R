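# Desk-scale synthetic fixtures: exhaustive enumeration of every chemically
# valid molecule up to a small heavy-atom count over a restricted element
# set.  Stands in for QM9/ChEMBL in tests and examples.  Fixture chemistry is
# neutral (charge 0) and stereo-free, hydrogens saturate free valences, and
# kekulized bond orders only are enumerated (aromaticity emerges, if at all,
# through RDKit's sanitization of the written molecule).

.MGM_VALENCE <- c(C = 4L, N = 3L, O = 2L, F = 1L)

#' Fixture specification
#'
#' @param max_heavy_atoms maximum number of heavy atoms (>= 1).
#' @param elements element set; each must have a known default valence
#'   (C, N, O, F).
#' @param bond_orders allowed bond orders between heavy atoms (subset of
#'   1:3 for single/double/triple).
#' @param allow_aromatic keep molecules whose canonical form contains
#'   aromatic atoms.  Default `FALSE`: at <= 4 heavy atoms the perception
#'   model flags some strained 3-membered N/O rings as aromatic (e.g.
#'   triaziridine written as an aromatic ring), which no chemist would call
#'   aromatic and which make the fixture distribution dominated by exotic
#'   species; a QM9 stand-in keeps plain kekulized chemistry.
#' @param seed seed used by downstream split shuffling.
#' @return an object of class `mgm_fixture_spec`.
#' @export
fixture_spec <- function(max_heavy_atoms = 4L, elements = c("C", "N", "O"),
                         bond_orders = 1:3, allow_aromatic = FALSE, seed = 1L) {
  stopifnot(max_heavy_atoms >= 1, length(elements) > 0,
            all(elements %in% names(.MGM_VALENCE)),
            all(bond_orders %in% 1:3))
  structure(list(max_heavy_atoms = as.integer(max_heavy_atoms),
                 elements = elements, bond_orders = as.integer(bond_orders),
                 allow_aromatic = isTRUE(allow_aromatic), seed = seed),
            class = "mgm_fixture_spec")
}

# connectivity of the bond skeleton (orders > 0), tiny n
.is_connected <- function(orders, pairs, n) {
  if (n == 1) return(TRUE)
  adj <- matrix(FALSE, n, n)
  on <- orders > 0
  if (!any(on)) return(FALSE)
  adj[pairs[on, , drop = FALSE]] <- TRUE
  adj <- adj | t(adj)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Exhaustively enumerate small molecules
#'
#' Enumerates every node-labelled multigraph within valence limits (connected
#' skeletons only; free valences filled with hydrogens), validates and
#' canonicalizes through the chemistry backend, deduplicates and sorts.
#' Deterministic for a fixed spec.
#'
#' @param spec an `mgm_fixture_spec` (or the `max_heavy_atoms` count).
#' @param elements,bond_orders used when `spec` is given as a plain count.
#' @return sorted character vector of canonical SMILES.
#' @export
enumerate_small_molecules <- function(spec, elements = c("C", "N", "O"),
                                      bond_orders = 1:3) {
  if (!inherits(spec, "mgm_fixture_spec")) {
    spec <- fixture_spec(spec, elements, bond_orders)
  }
  nmax <- spec$max_heavy_atoms
  elems <- spec$elements
  orders <- sort(unique(c(0L, spec$bond_orders)))
  est <- sum(vapply(seq_len(nmax), function(n)
    length(elems)^n * length(orders)^(n * (n - 1) / 2), numeric(1)))
  if (est > 5e7) {
    stop(sprintf(paste0("enumerate_small_molecules: refusing to enumerate ",
                        "an estimated %.3g labelled graphs; shrink ",
                        "max_heavy_atoms or the element set"), est), call. = FALSE)
  }
  val <- .MGM_VALENCE[elems]
  payloads <- list()
  for (n in seq_len(nmax)) {
    if (n == 1) {
      for (el in elems) {
        payloads[[length(payloads) + 1L]] <- list(
          symbol = el, num_h = as.integer(.MGM_VALENCE[[el]]), charge = 0L,
          chirality = "unspecified", aromatic = FALSE,
          bond_i = integer(0), bond_j = integer(0), bond_type = character(0))
      }
      next
    }
    pairs <- graph_pairs(n)
    P <- nrow(pairs)
    A <- as.matrix(expand.grid(rep(list(orders), P)))  # assignments x P
    inc <- matrix(0L, P, n)
    for (p in seq_len(P)) inc[p, pairs[p, ]] <- 1L
    deg <- A %*% inc                                   # bond-order sum per node
    keep <- which(apply(deg, 1, max) <= max(val) & apply(deg, 1, min) >= 1L)
    keep <- keep[vapply(keep, function(r) .is_connected(A[r, ], pairs, n), logical(1))]
    if (length(keep) == 0) next
    labelings <- as.matrix(expand.grid(rep(list(seq_along(elems)), n)))
    lab_val <- matrix(val[labelings], nrow(labelings), n)
    bt <- c("single", "double", "triple")
    for (r in keep) {
      ords <- A[r, ]
      d <- deg[r, ]
      ok <- which(apply(lab_val >= rep(d, each = nrow(lab_val)), 1, all))
      on <- which(ords > 0)
      for (li in ok) {
        payloads[[length(payloads) + 1L]] <- list(
          symbol = elems[labelings[li, ]],
          num_h = as.integer(lab_val[li, ] - d),
          charge = rep(0L, n),
          chirality = rep("unspecified", n),
          aromatic = rep(FALSE, n),
          bond_i = as.integer(pairs[on, "i"] - 1L),
          bond_j = as.integer(pairs[on, "j"] - 1L),
          bond_type = bt[ords[on]])
      }
    }
  }
  out <- chem_call("write", list(graphs = payloads))$smiles
  smi <- vapply(out, function(x) if (is.null(x)) NA_character_ else x, character(1))
  smi <- sort(unique(smi[!is.na(smi)]))
  if (!spec$allow_aromatic && length(smi) > 0) {
    parsed <- chem_parse(smi)
    arom <- vapply(parsed, function(p) any(as.logical(p$atoms$aromatic)), logical(1))
    smi <- smi[!arom]
  }
  smi
}

#' Write a fixture SMILES file
#'
#' Convenience wrapper: enumerate, then write one molecule per line.
#'
#' @param spec an `mgm_fixture_spec`.
#' @param path output file.
#' @return the SMILES vector, invisibly.
#' @export
write_fixture_file <- function(spec, path) {
  smi <- enumerate_small_molecules(spec)
  writeLines(smi, path)
  invisible(smi)
}
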