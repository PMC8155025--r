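# Molecular-graph data model: a molecule is a complete graph over its heavy
# atoms.  Every node carries 6 categorical properties, every unordered node
# pair ("prospective edge") carries one categorical edge type, where "none"
# (no bond) is a first-class category.  Each property additionally reserves a
# MASK index used by the corruption process and the sampler.

MGM_NODE_PROPS <- c("atom_type", "num_h", "charge", "chirality", "in_ring", "aromatic")
MGM_EDGE_TYPES <- c("none", "single", "double", "triple", "aromatic")
MGM_CHIRALITY  <- c("unspecified", "cw", "ccw", "other")

#' Build a vocabulary from a set of SMILES strings
#'
#' Scans a training corpus and records, for each of the six node properties
#' and the single edge property, the ordered list of real categories plus one
#' reserved MASK index (always the last index).  Atom types are sorted
#' alphabetically, hydrogen counts ascending, and the charge list spans the
#' full integer range from the minimum to the maximum observed charge.
#' Chirality, ring-membership, aromaticity and bond type have fixed category
#' lists independent of the data.
#'
#' @param smiles_list character vector of SMILES, all of which must parse and
#'   sanitize; an unparsable entry is an error naming the offending line.
#' @return an object of class `mgm_vocab`.
#' @export
build_vocabulary <- function(smiles_list) {
  if (length(smiles_list) == 0) stop("build_vocabulary: empty input", call. = FALSE)
  parsed <- chem_parse(smiles_list)
  bad <- which(!vapply(parsed, function(p) isTRUE(p$ok), logical(1)))
  if (length(bad) > 0) {
    stop(sprintf("build_vocabulary: unparsable SMILES at line(s) %s (first: '%s')",
                 paste(utils::head(bad, 5), collapse = ", "),
                 smiles_list[bad[1]]), call. = FALSE)
  }
  syms <- sort(unique(unlist(lapply(parsed, function(p) p$atoms$symbol))))
  nhs  <- sort(unique(unlist(lapply(parsed, function(p) as.integer(p$atoms$num_h)))))
  chg  <- unlist(lapply(parsed, function(p) as.integer(p$atoms$charge)))
  vocab <- list(
    node = list(
      atom_type = list(categories = syms),
      num_h     = list(categories = nhs),
      charge    = list(categories = seq(min(chg), max(chg))),
      chirality = list(categories = MGM_CHIRALITY),
      in_ring   = list(categories = c(FALSE, TRUE)),
      aromatic  = list(categories = c(FALSE, TRUE))
    ),
    edge = list(categories = MGM_EDGE_TYPES)
  )
  for (k in seq_along(vocab$node)) {
    vocab$node[[k]]$mask_index <- length(vocab$node[[k]]$categories) + 1L
  }
  vocab$edge$mask_index <- length(MGM_EDGE_TYPES) + 1L
  structure(vocab, class = "mgm_vocab")
}

#' Number of real categories of a node property (MASK excluded)
#' @param vocab an `mgm_vocab`.
#' @param prop property name or index (1..6).
#' @export
vocab_n_categories <- function(vocab, prop) {
  length(vocab$node[[prop]]$categories)
}

#' Serialize / deserialize a vocabulary as JSON
#' @param vocab an `mgm_vocab`.
#' @param path file path.
#' @export
vocab_write_json <- function(vocab, path) {
  jsonlite::write_json(unclass(vocab), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname vocab_write_json
#' @export
vocab_read_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$node <- lapply(raw$node, function(p) {
    p$mask_index <- as.integer(p$mask_index)
    p
  })
  # restore native types lost by JSON
  raw$node$num_h$categories  <- as.integer(raw$node$num_h$categories)
  raw$node$charge$categories <- as.integer(raw$node$charge$categories)
  raw$node$in_ring$categories  <- as.logical(raw$node$in_ring$categories)
  raw$node$aromatic$categories <- as.logical(raw$node$aromatic$categories)
  raw$edge$mask_index <- as.integer(raw$edge$mask_index)
  structure(raw, class = "mgm_vocab")
}

#' Unordered node pairs of an N-node complete graph
#'
#' Pair slots are stored once per unordered pair (i < j), in column-major
#' upper-triangular order: (1,2), (1,3), (2,3), (1,4), ...  This ordering is
#' the single storage convention for prospective edges everywhere in the
#' package.
#'
#' @param n number of nodes.
#' @return integer matrix with columns `i`, `j` and `n*(n-1)/2` rows.
#' @export
graph_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

#' Index of the pair slot for nodes (i, j)
#' @param i,j node indices (order irrelevant).
#' @param n number of nodes.
#' @export
pair_index <- function(i, j, n) {
  lo <- unname(pmin(i, j)); hi <- unname(pmax(i, j))
  ((hi - 1L) * (hi - 2L)) %/% 2L + lo
}

new_graph <- function(nodes, edges, y = NULL) {
  structure(list(n = nrow(nodes), nodes = nodes, edges = edges, y = y),
            class = "mgm_graph")
}

#' @export
print.mgm_graph <- function(x, ...) {
  cat(sprintf("<mgm_graph: %d nodes, %d prospective edges%s>\n",
              x$n, length(x$edges),
              if (!is.null(x$y)) sprintf(", y=%.4g", x$y) else ""))
  invisible(x)
}

graph_has_mask <- function(graph, vocab) {
  masks <- vapply(vocab$node, `[[`, integer(1), "mask_index")
  any(sweep(graph$nodes, 2, masks, "==")) || any(graph$edges == vocab$edge$mask_index)
}

.graph_from_parsed <- function(p, vocab, smiles = "") {
  n <- length(p$atoms$symbol)
  cat_index <- function(values, prop) {
    idx <- match(values, vocab$node[[prop]]$categories)
    if (anyNA(idx)) {
      stop(sprintf("smiles_to_graph: value '%s' of property '%s' not in vocabulary (input '%s')",
                   values[which(is.na(idx))[1]], prop, smiles), call. = FALSE)
    }
    as.integer(idx)
  }
  nodes <- cbind(
    atom_type = cat_index(p$atoms$symbol, "atom_type"),
    num_h     = cat_index(as.integer(p$atoms$num_h), "num_h"),
    charge    = cat_index(as.integer(p$atoms$charge), "charge"),
    chirality = cat_index(p$atoms$chirality, "chirality"),
    in_ring   = cat_index(as.logical(p$atoms$in_ring), "in_ring"),
    aromatic  = cat_index(as.logical(p$atoms$aromatic), "aromatic")
  )
  edges <- rep(1L, (n * (n - 1L)) %/% 2L)  # 1 == "none"
  if (length(p$bonds$i) > 0) {
    bi <- as.integer(p$bonds$i) + 1L  # helper is 0-based
    bj <- as.integer(p$bonds$j) + 1L
    bt <- match(p$bonds$type, MGM_EDGE_TYPES)
    edges[pair_index(bi, bj, n)] <- as.integer(bt)
  }
  new_graph(nodes, edges)
}

#' Convert a SMILES string to a featurized molecular graph
#'
#' Node order follows RDKit's atom order for the parsed input (a recorded
#' convention, not a semantic guarantee).  Every non-bonded node pair gets the
#' explicit edge type `"none"`; hydrogen counts are stored as a node property
#' and are authoritative on reconstruction.
#'
#' @param smiles a single SMILES string.
#' @param vocab an `mgm_vocab` covering all property values of the molecule.
#' @return an `mgm_graph` with no MASK indices.
#' @export
smiles_to_graph <- function(smiles, vocab) {
  smiles_to_graphs(smiles, vocab)[[1]]
}

#' @rdname smiles_to_graph
#' @param smiles_list character vector (batch form; one python round-trip).
#' @export
smiles_to_graphs <- function(smiles_list, vocab) {
  parsed <- chem_parse(smiles_list)
  lapply(seq_along(parsed), function(k) {
    p <- parsed[[k]]
    if (!isTRUE(p$ok)) {
      stop(sprintf("smiles_to_graph: cannot parse '%s' (line %d)", smiles_list[k], k),
           call. = FALSE)
    }
    .graph_from_parsed(p, vocab, smiles_list[k])
  })
}

.graph_payload <- function(graph, vocab) {
  cat_of <- function(prop) vocab$node[[prop]]$categories[graph$nodes[, prop]]
  pr <- graph_pairs(graph$n)
  bonded <- which(graph$edges != 1L)
  # atomic vectors (not lists) so jsonlite emits flat JSON arrays
  list(
    symbol = as.character(cat_of("atom_type")),
    num_h = as.integer(cat_of("num_h")),
    charge = as.integer(cat_of("charge")),
    chirality = as.character(cat_of("chirality")),
    aromatic = as.logical(cat_of("aromatic")),
    bond_i = as.integer(pr[bonded, "i"] - 1L),
    bond_j = as.integer(pr[bonded, "j"] - 1L),
    bond_type = as.character(MGM_EDGE_TYPES[graph$edges[bonded]])
  )
}

#' Convert molecular graphs back to canonical SMILES
#'
#' Rebuilds an RDKit molecule from the stored properties (explicit hydrogen
#' counts, bond orders, charges, chirality tags, aromatic flags) and
#' sanitizes it.  A graph that fails sanitization — a chemically impossible
#' molecule — yields `NA` and counts as invalid downstream; it is never
#' repaired.  Disconnected graphs come back as dot-separated multi-fragment
#' SMILES.  A MASK index anywhere is a contract violation (error), distinct
#' from chemical invalidity.
#'
#' @param graph an `mgm_graph` (or a list of them for `graphs_to_smiles`).
#' @param vocab the matching `mgm_vocab`.
#' @return canonical SMILES string, or `NA_character_` on sanitization failure.
#' @export
graph_to_smiles <- function(graph, vocab) {
  graphs_to_smiles(list(graph), vocab)[[1]]
}

#' @rdname graph_to_smiles
#' @param graphs list of `mgm_graph` (batch form; one python round-trip).
#' @export
graphs_to_smiles <- function(graphs, vocab) {
  for (g in graphs) {
    if (graph_has_mask(g, vocab)) {
      stop("graph_to_smiles: graph contains MASK indices (contract violation)",
           call. = FALSE)
    }
  }
  out <- chem_call("write", list(graphs = lapply(graphs, .graph_payload, vocab = vocab)))$smiles
  vapply(out, function(x) {
    if (is.null(x) || length(x) != 1 || is.na(x)) NA_character_ else as.character(x)
  }, character(1), USE.NAMES = FALSE)
}

# Atomic masses for the graph-level molecular-weight property used by the
# conditional generator at fixture scale (heavy atoms + explicit hydrogens).
.MGM_MASSES <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.45,
                 Se = 78.971, Br = 79.904, I = 126.904)

#' Molecular weight of a graph from stored properties
#'
#' Sum of heavy-atom masses plus explicit hydrogens; computable without the
#' chemistry backend, hence usable inside tight sampling loops and as the
#' conditional-generation target property at fixture scale.
#'
#' @param graph an `mgm_graph` with no MASK indices.
#' @param vocab the matching `mgm_vocab`.
#' @return numeric scalar (g/mol).
#' @export
graph_mol_weight <- function(graph, vocab) {
  syms <- vocab$node$atom_type$categories[graph$nodes[, "atom_type"]]
  nh <- as.integer(vocab$node$num_h$categories[graph$nodes[, "num_h"]])
  sum(.MGM_MASSES[syms]) + sum(nh) * .MGM_MASSES[["H"]]
}
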