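Package: brafpocket
Title: Structure-Energy and Mutational-Accessibility Modelling of BRAF
    Hotspot Mutation Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting why some activating kinase mutations
    dominate somatic cancer catalogues while energetically similar ones are
    rare, built around the BRAF activation-segment hydrophobic pocket.
    Post-processes per-mutation folding free-energy (ddG) tables computed on
    active- and inactive-state crystal structure templates, derives
    per-residue resolved-fraction and normalized B-factor flexibility
    profiles from structure ensembles, applies flexibility and phosphomimetic
    salt-bridge corrections, computes codon-level mutational accessibility
    (minimum nucleotide substitutions and codon-usage change), assembles a
    seven-predictor feature matrix against transformed mutation counts, and
    quantifies each predictor's contribution with a balanced random-forest
    regression protocol using node-impurity importance. Includes a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    graphics,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
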