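#' @keywords internal
"_PACKAGE"

# Bridge to the bundled RDKit helper (inst/python/chemtool.py).  All chemistry
# primitives (parsing, sanitization, canonicalization, descriptors) go through
# here in batches: one python process per call, arbitrarily many molecules.

.maskmol_env <- new.env(parent = emptyenv())

chem_python <- function() {
  p <- getOption("maskmol.python", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) {
    stop("maskmol: no `python` found on PATH (needed for the RDKit chemistry backend)",
         call. = FALSE)
  }
  p
}

chem_script <- function() {
  s <- system.file("python", "chemtool.py", package = "maskmol")
  if (!nzchar(s)) stop("maskmol: bundled chemtool.py not found; is the package installed?",
                       call. = FALSE)
  s
}

#' Low-level call into the RDKit helper
#'
#' @param op one of "parse", "write", "canon", "descr", "simmax", "ping".
#' @param payload a list serialized to JSON for the helper.
#' @return the helper's JSON output, parsed with vector simplification.
#' @keywords internal
chem_call <- function(op, payload) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = FALSE, digits = NA, null = "null")
  err <- tempfile(fileext = ".txt")
  on.exit(unlink(err), add = TRUE)
  status <- suppressWarnings(
    system2(chem_python(), c(shQuote(chem_script()), op, shQuote(fin), shQuote(fout)),
            stdout = FALSE, stderr = err)
  )
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(err, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop(sprintf("maskmol chemistry backend failed (op=%s, status=%s):\n%s",
                 op, status, msg), call. = FALSE)
  }
  jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

#' Parse SMILES strings into raw RDKit feature lists (batch)
#' @param smiles character vector.
#' @return list with one entry per molecule: ok, error, canonical, atoms, bonds.
#' @keywords internal
chem_parse <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  chem_call("parse", list(smiles = smiles))$results
}

#' Canonicalize SMILES (batch); NA for strings that fail parse/sanitize
#' @param smiles character vector.
#' @return character vector of canonical SMILES, NA where invalid.
#' @export
chem_canonicalize <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  out <- chem_call("canon", list(smiles = as.character(smiles)))$canonical
  vapply(out, function(x) {
    if (is.null(x) || length(x) != 1 || is.na(x)) NA_character_ else as.character(x)
  }, character(1), USE.NAMES = FALSE)
}

#' Physiochemical descriptor table (batch)
#'
#' Computes the GuacaMol KL-divergence benchmark descriptor set for each
#' molecule: BertzCT, MolLogP, MolWt, TPSA, NumHAcceptors, NumHDonors,
#' NumRotatableBonds, NumAliphaticRings, NumAromaticRings.
#'
#' @param smiles character vector of SMILES.
#' @return data.frame of descriptors, one row per input; NA rows where invalid.
#' @export
chem_descriptors <- function(smiles) {
  stopifnot(length(smiles) > 0)
  out <- chem_call("descr", list(smiles = as.character(smiles)))
  cols <- lapply(out$descriptors, function(col)
    vapply(col, function(x) if (is.null(x)) NA_real_ else as.numeric(x), numeric(1)))
  as.data.frame(cols, optional = TRUE)
}

#' Per-molecule maximum Tanimoto similarity within a sample (batch)
#' @param smiles character vector.
#' @param radius,n_bits Morgan fingerprint parameters.
#' @return numeric vector; NA where invalid or sample too small.
#' @keywords internal
chem_simmax <- function(smiles, radius = 2, n_bits = 2048) {
  out <- chem_call("simmax", list(smiles = as.character(smiles),
                                  radius = radius, n_bits = n_bits))$simmax
  vapply(out, function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x), numeric(1), USE.NAMES = FALSE)
}
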