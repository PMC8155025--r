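Package: maskmol
Title: Masked Graph Models for Small-Molecule Generation
Version: 0.1.0
Authors@R:
    person("maskmol", "developers", email = "maskmol@example.org", role = c("aut", "cre"))
Description: Learns conditional distributions of masked atoms and bonds in
    molecular graphs with a tied-weight message passing neural network, and
    generates molecules by Gibbs-style iterative masked resampling.  Supports
    unconditional and property-conditional generation, exhaustive small-molecule
    fixture enumeration, and GuacaMol-style distribution-learning metrics
    (validity, uniqueness, novelty, KL-divergence score, Frechet hook).
    Chemistry primitives (SMILES parsing, sanitization, canonicalization,
    descriptors) are delegated to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
SystemRequirements: python (>= 3.8) with rdkit importable, on PATH
Config/testthat/edition: 3
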