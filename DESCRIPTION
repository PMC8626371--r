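Package: isofine
Title: Natural Isotope Abundance Correction for Labelled Metabolites and
    Modified Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Corrects isotopologue intensities measured in stable-isotope
    labelling experiments for naturally occurring heavy isotopes. Builds a
    skewed correction matrix from the isotopic fine structure of each
    isotopologue's residual (unlabelled) atoms, merges fine-structure species
    that are indistinguishable at the instrument's resolving power (Orbitrap
    inverse-square-root scaling supported), and inverts the contamination by
    forward substitution. Handles incomplete isotopologue sets, multiple
    simultaneous tracer isotopes (e.g. 13C and 15N), peptides with
    post-translational modifications, and label-incorporation dynamics via
    linear slope fitting. Includes a forward-simulation module for
    validation and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
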