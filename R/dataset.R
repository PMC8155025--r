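# Datasets: a list of featurized graphs plus the canonical-SMILES set used by
# the novelty metric and the vocabulary builder.

new_dataset <- function(graphs, smiles, split = "train") {
  structure(list(graphs = graphs, smiles = smiles,
                 canonical_set = unique(smiles), split = split),
            class = "mgm_dataset")
}

#' @export
print.mgm_dataset <- function(x, ...) {
  cat(sprintf("<mgm_dataset '%s': %d graphs, %d distinct canonical SMILES>\n",
              x$split, length(x$graphs), length(x$canonical_set)))
  invisible(x)
}

#' Build a dataset from in-memory SMILES
#'
#' @param smiles character vector of SMILES.
#' @param vocab an `mgm_vocab`; built from `smiles` when `NULL`.
#' @param on_error `"abort"` (default) stops at the first unparsable entry;
#'   `"skip"` drops bad entries with a warning listing their line numbers.
#' @param split split label carried on the dataset.
#' @return an `mgm_dataset`.
#' @export
dataset_from_smiles <- function(smiles, vocab = NULL, on_error = c("abort", "skip"),
                                split = "train") {
  on_error <- match.arg(on_error)
  if (length(smiles) == 0) stop("dataset_from_smiles: empty input", call. = FALSE)
  parsed <- chem_parse(smiles)
  ok <- vapply(parsed, function(p) isTRUE(p$ok), logical(1))
  if (any(!ok)) {
    if (on_error == "abort") {
      stop(sprintf("dataset_from_smiles: unparsable SMILES at line(s) %s",
                   paste(which(!ok), collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("dataset_from_smiles: skipped %d unparsable line(s): %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
    parsed <- parsed[ok]
    smiles <- smiles[ok]
  }
  if (is.null(vocab)) vocab <- build_vocabulary(smiles)
  graphs <- lapply(seq_along(parsed), function(k)
    .graph_from_parsed(parsed[[k]], vocab, smiles[k]))
  canon <- vapply(parsed, function(p) p$canonical, character(1))
  ds <- new_dataset(graphs, canon, split)
  ds$vocab <- vocab
  ds
}

#' Load a dataset from a SMILES file
#'
#' One molecule per line, UTF-8, blank lines ignored.
#'
#' @param path path to a SMILES text file.
#' @inheritParams dataset_from_smiles
#' @return an `mgm_dataset`.
#' @export
load_dataset <- function(path, vocab = NULL, on_error = c("abort", "skip"),
                         split = "train") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop(sprintf("load_dataset: no molecules in '%s'", path),
                               call. = FALSE)
  dataset_from_smiles(lines, vocab, on_error, split)
}

#' Reproducible train/validation split
#'
#' @param dataset an `mgm_dataset`.
#' @param frac fraction of graphs assigned to the training split.
#' @param seed RNG seed fixing the shuffle.
#' @return list with elements `train` and `valid`, both `mgm_dataset`.
#' @export
split_dataset <- function(dataset, frac = 0.8, seed = 1L) {
  m <- length(dataset$graphs)
  stopifnot(m >= 2, frac > 0, frac < 1)
  idx <- with_seed_opt(seed, sample.int(m))
  n_tr <- max(1L, min(m - 1L, floor(frac * m)))
  take <- function(ix, label) {
    ds <- new_dataset(dataset$graphs[ix], dataset$smiles[ix], label)
    ds$vocab <- dataset$vocab
    ds
  }
  list(train = take(idx[seq_len(n_tr)], "train"),
       valid = take(idx[(n_tr + 1L):m], "valid"))
}
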