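Package: gsmerge
Title: Semi-Automatic Consensus Reconstruction of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges two or more genome-scale constraint-based metabolic models of the
    same organism into a consensus model. Detects and reconciles inconsistencies at the
    metabolite level (network-context metabolite matching), the reaction level (identical
    net reactions, alternative stoichiometries, redox-pair variants, nested, similar and
    lumped reactions), and the compartment level (transport splitting, compartment removal,
    boundary-reaction repair). Reads and writes the constraint-based subset of SBML, keeps
    a replayable decision log, and evaluates merged models by flux-balance growth-phenotype
    prediction (sensitivity, specificity, accuracy, Matthews correlation coefficient).
    Includes a synthetic-fixture generator that plants labelled instances of every
    inconsistency class for testing and benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
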