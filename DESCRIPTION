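Package: hml2ltr
Title: HERV-K (HML-2) LTR Subtype Discovery, Motif Profiling, and Reporter Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterizing the three long terminal repeat (LTR)
    subtypes of the human endogenous retrovirus K (HML-2) family: k-mer
    seeded discovery of LTR-like loci against subtype consensus references,
    length screening and consensus-identity subtype classification, Kimura
    two-parameter neighbor-joining phylogeny with bootstrap support,
    IUPAC consensus motif frequency profiling of the TSS-proximal
    enhancer/core-promoter fragment, GREAT-style basal-plus-extension gene
    association, in-silico reporter construct design (section-replacement
    chimeras and site-directed mutants), and quantification of
    dual-luciferase and qPCR readouts. Includes a seeded synthetic-data
    generator with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
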