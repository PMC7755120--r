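Package: mtscreen
Title: Screening Mitochondrial tRNA Variants for Pathogenic Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies human mitochondrial tRNA variants as putatively
    pathogenic versus polymorphic using a three-criterion screen:
    interspecies conservation index, control-cohort allele frequency, and
    predicted cloverleaf structural or functional impact (Watson-Crick
    stem-pair disruption, tertiary interaction sites).  Includes a
    validated cloverleaf structure model of all 22 human mt-tRNA genes
    with conventional position numbering, readers for variant tables and
    per-gene multi-species alignments, seeded synthetic-data generators,
    cohort clinical summaries, and report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
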