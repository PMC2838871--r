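Package: safrag
Title: Density-Based Structural Alphabets for Protein Backbone Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps protein C-alpha backbones into a three-angle fragment space
    (two pseudo-bond angles and one pseudo-torsion per four-residue fragment),
    derives Structural Alphabets from the density structure of that space via
    OPTICS ordering and Drop-Down hierarchical cluster extraction, and encodes
    or reconstructs backbones with the bundled 25-letter M32K25 alphabet.
    Includes local (per-window best fit) and global (beam-search fragment
    assembly) encoders with AIC-based alphabet ranking, Gaussian Network Model
    analysis of native versus reconstructed structures (RMSF profiles and
    cross-correlation matrix overlap), Shannon-entropy profiling of encoded
    conformational ensembles, and a synthetic-data generator for chains,
    perturbed ensembles and labelled angle-space clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
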