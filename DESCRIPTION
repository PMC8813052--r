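Package: idrseq
Title: Sequence Feature Analysis and Variant Design for Intrinsically
    Disordered Regions
Version: 0.1.0
Authors@R: person("idrseq", "maintainers", email = "idrseq@example.org",
    role = c("aut", "cre"))
Description: Toolkit for profiling intrinsically disordered protein
    regions (IDRs) from primary sequence: amino-acid composition and
    heatmap matrices, Shannon sequence complexity, Kyte-Doolittle
    hydropathy, charge-patterning metrics (FCR, NCPR, Das-Pappu kappa,
    isoelectric point), sliding-window tracks, hydrophobic run-length
    statistics and CDK consensus-site scanning. Includes a
    disorder-track segmentation pipeline for proteome-scale
    ordered/disordered domain comparisons, composition-preserving
    sequence-variant designers (scramble, uniform charge
    redistribution, residue substitution, deletions) with dotplot
    verification, and seeded synthetic-data generators for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
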