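Package: connmap
Title: Directional Drug-Protein Connectivity Maps for Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds directional drug-to-protein connectivity maps from
    signed evidence records and a confidence-weighted protein-protein
    interaction network, scoring each drug-protein pair with a
    pharmacology score that combines aggregated evidence confidence and
    network-derived protein weights. Supports systematic drug
    repositioning through signed-Tanimoto drug similarity with
    guilt-by-association indication transfer (leave-one-out ROC/AUC
    evaluation) and Kolmogorov-Smirnov connectivity scoring of disease
    gene signatures against ranked drug profiles with permutation
    significance and star ratings. Includes a synthetic benchmark
    generator with planted drug-disease structure and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
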