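Package: smorfscan
Title: Identification, Classification and Expression Analysis of Small Open
    Reading Frames
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide discovery of small open reading frames (smORFs, at
    most 100 codons) from assembled transcripts and multi-species conserved
    genomic regions, using a species-specific Kozak start-codon model that
    admits near-cognate starts. Candidates are tiered by coding-potential and
    homology evidence (HC1-HC3, LC1-LC2) and placed into positional categories
    (InFrameORF, OutFrameORF, uORF, dORF, ncORF, intronORF, intergenicORF) by
    a priority rule against a gene annotation. Downstream modules provide
    union-mode fragment counting with parent-gene count inheritance for
    smORFs, FPKM/TPM normalisation, pairwise differential expression with an
    FDR and fold-change double gate, and the tissue-specificity index (TSI).
    A seeded synthetic-data generator plants smORFs of every category, with
    conservation evidence and negative-binomial expression, so the whole
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GenomeAnnotation, GeneExpression,
    DifferentialExpression, Sequencing
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'analysis.R'
    'coords.R'
    'kozak.R'
    'scan.R'
    'discover.R'
    'classify.R'
    'io.R'
    'synthesize.R'
    'quantify.R'
    'pipeline.R'
    'utils.R'
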