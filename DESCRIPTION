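Package: giantvirion
Title: Giant-Virus Virion Architecture, Packaged-Proteome Quantification,
    and Environmental Lyase Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the computational characterization of giant
    (nucleocytoplasmic large DNA) virus particles. Implements closed-form
    arithmetic of quasi-equivalent icosahedral capsid lattices
    (triangulation numbers, capsomer and major-capsid-protein copy
    budgets, trisymmetron/pentasymmetron decomposition), anchor-based
    conversion of label-free MS1 intensities into protein
    copies-per-particle, reciprocal-best-hit comparison of packaged
    proteomes with presence/absence clustering, and a rule-based screen
    for virus-encoded polysaccharide lyases on assembled metagenomic
    contigs. A synthetic-data module generates proteomes, hit tables,
    intensity tables, and metagenomes with planted ground truth so the
    full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    ape,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
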