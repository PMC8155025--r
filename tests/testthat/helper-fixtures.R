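# Shared, lazily-built expensive objects (chemistry backend calls are slow to
# start, so fixtures are enumerated/parsed once per test run and cached here).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# small mixed corpus exercising every property family
toy_smiles <- function() c("C", "CCO", "c1ccccc1", "CC(=O)N", "CNO", "CC#N", "C1CC1")

toy_vocab <- function() cached("toy_vocab", build_vocabulary(toy_smiles()))

toy_graphs <- function() cached("toy_graphs", smiles_to_graphs(toy_smiles(), toy_vocab()))

# exhaustive <= 3-heavy-atom C/N/O set (used where the full 4-atom set would
# be overkill)
fixture3 <- function() cached("fixture3",
  enumerate_small_molecules(fixture_spec(3, c("C", "N", "O"))))

# the full <= 4-heavy-atom C/N/O fixture set (QM9 stand-in)
fixture4 <- function() cached("fixture4",
  enumerate_small_molecules(fixture_spec(4, c("C", "N", "O"))))

fixture4_dataset <- function() cached("fixture4_dataset", {
  smi <- fixture4()
  v <- build_vocabulary(smi)
  ds <- dataset_from_smiles(smi, vocab = v)
  ds$vocab <- v
  ds
})
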