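Package: heatSpliceNet
Title: Time-Course Splicing Co-Expression Networks for Heat-Stress Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds transcript-level splicing regulatory networks from
    time-course RNA-seq quantifications. Transcript TPM profiles are
    replicate-averaged and Z-scored, differential-transcript-usage (DTU)
    transcripts are grouped into co-expressed modules by soft-threshold
    weighted correlation, topological overlap, average-linkage hierarchical
    clustering and a hybrid dynamic tree cut, and module centroids are
    correlated against candidate splicing-factor/RNA-binding-protein
    transcripts to form a bipartite regulator network thresholded at a top
    percentile of correlation coefficients with early/late temporal
    classification. Also provides transcript-level isoform-proportion
    tracks, isoform-switch detection, the 50-nt exon-junction rule for
    nonsense-mediated decay targeting, and a seedable synthetic time-course
    generator with planted modules, regulators and isoform switches for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    ape,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
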