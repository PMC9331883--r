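Package: LiPDARTS
Title: Drug-Target Deconvolution by DARTS Protection Scoring and Targeted
    Limited-Proteolysis MRM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for label-free drug-target deconvolution in
    crude lysates. Implements DARTS (drug affinity responsive target
    stability) protection percentages across a ligand concentration series
    with replicate Venn intersection and target ranking; targeted limited
    proteolysis (t-LiP-MRM) analysis including in-silico tryptic and
    semi-tryptic digestion, peptide and fragment-ion mass arithmetic, MRM
    transition candidate design, chromatographic peak integration,
    LiP-peptide selection, ligand fold changes and mapping of protected
    peptides onto structural annotation tracks; and supporting quantitative
    pharmacology (percent-growth GI50 fitting with a four-parameter
    logistic, PAMPA effective permeability, coupled enzymatic assay
    kinetics, and free-energy to dissociation-constant conversion). A
    seeded synthetic-data generator with planted ground truth drives all
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
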