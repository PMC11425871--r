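Package: neo3d
Title: 3D-Genome-Augmented Prediction of MHC-II Neoantigen Immunogenicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline testing whether features derived from the
    3D organisation of the genome (chromatin coordinates and radial nuclear
    position of a peptide's DNA locus) improve prediction of MHC class II
    neoantigen immunogenicity over a sequence-based baseline score. Provides
    curation of T-cell assay records into labelled peptide datasets, offline
    mapping of peptides to genomic loci, compartment-degree estimation from
    Hi-C contact matrices, bead-on-string whole-genome 3D reconstruction
    under connectivity and radial-activity restraints, 9-feature assembly,
    and repeated cross-validation evaluation with KNN, SVM and logistic
    regression. A synthetic-data module generates ground-truth structures,
    contact maps, gene annotations and labelled peptide datasets so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
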