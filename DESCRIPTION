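Package: isomix
Title: Structural Classification, Quality Control and Mixture-Model
    Stratification of Full-Length Transcript Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing full-length (long-read) transcript isoform
    catalogs against a reference annotation: SQANTI-style structural
    classification (FSM/ISM/NIC/NNC and friends), artifact-aware quality
    filtering (poly(A) intrapriming, RT-switching, noncanonical junctions,
    short-read junction support, intron retention), protein-level consequence
    annotation (ORF selection, global identity to a reference proteome,
    domain/transmembrane/localization deltas, nonsense-mediated decay
    prediction, peptide-support classes, ribosome-occupancy translation
    cutoffs), local alternative-splicing event extraction with
    percent-spliced-in quantification, Jaccard similarity clustering of
    sample isoform sets, and a Gaussian-mixture patient-stratification
    procedure that detects tumor-specific, survival-associated splicing
    events. A synthetic-data generator produces toy genomes, annotations,
    isoform catalogs and cohorts with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
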