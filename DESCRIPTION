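Package: resensitizer
Title: Drug-Specific Genes and Transcriptional-Reversal Ranking of Sensitizers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies drug-specific genes (DSGs) by correlating basal gene
    expression with drug response (IC50) across cancer cell lines, with an
    extreme-cell-line refinement, and ranks candidate sensitizer compounds by a
    response-informed score that rewards selective inversion of resistance- and
    sensitivity-associated DSGs in Connectivity-Map-style perturbation
    profiles. Also provides drug-drug similarity by DSG-set Tanimoto overlap,
    continuous correlation profiles and chemical-structure fingerprints,
    hypergeometric Hallmark-style overrepresentation analysis, readers and
    writers for the tabular formats involved (expression and response
    matrices, long-form and GCT v1.3 perturbation profiles, GMT gene sets,
    SMILES tables), and a synthetic pharmacogenomic data generator with
    planted DSG structure and planted sensitizers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Pharmacogenomics, GeneExpression, Transcriptomics, Cheminformatics
RoxygenNote: 7.3.3
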