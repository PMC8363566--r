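Package: rifaquant
Title: Quantification of Salivary Gland Interstitial Fibrosis and Its
    Downstream Molecular Correlates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the relative interstitial fibrosis area (RIFA)
    score for Masson's trichrome-stained salivary gland sections, from
    pathologist-style polygon annotations or by automated stain
    deconvolution and segmentation, together with the downstream
    analyses that link fibrosis to gland hypofunction and a
    fibroblast-centred gene program: quantile normalisation,
    detection-flag filtering, differential expression and gene-set
    intersection for microarray intensities; Pearson screening of gene
    expression against RIFA; single-cell QC, log-normalisation,
    per-cell-type averaging and the percent-of-total-expression
    statistic with a fibroblast enrichment test; and promoter
    accessibility analysis (1-kb upstream promoter construction and
    merging, per-base coverage, region means, set comparisons) with a
    position-weight-matrix motif scanner and transcription-factor
    ranking. A seeded synthetic-data layer generates trichrome images,
    expression matrices, single-cell counts and a toy genome with
    coverage, all with known ground truth, so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    SingleCellExperiment,
    rtracklayer,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Software, Transcriptomics, SingleCell, Epigenetics,
    CellBiology
RoxygenNote: 7.3.3
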