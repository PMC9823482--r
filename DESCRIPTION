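Package: todcourse
Title: Time-of-Day Expression Analysis over Developmental Time Courses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-of-day (TOD) analysis of diurnal expression time
    courses sampled repeatedly over a developmental season, as in field-grown
    rice profiled every two hours over 48 h at eleven developmental stages.
    Provides quantile normalization, HAYSTACK-style rhythmicity detection by
    correlation against a library of phased waveform templates, circular
    phase-shift analyses between developmental stages (baseline anchor and
    incremental proximal comparisons), ELEMENT-style promoter 3-8 bp kmer
    overrepresentation with motif clustering and TOD significance profiles,
    phase-binned GO term enrichment with cross-stage overlap summaries, and
    sample-similarity QC (correlation matrix, classical MDS, cycling-set
    overlaps). A seeded synthetic-data generator emulates the statistical
    structure of such experiments (planted waveforms, phases, promoter
    elements and GO enrichments) so that every stage is testable by parameter
    recovery without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
biocViews: GeneExpression, TimeCourse, Transcriptomics, Normalization,
    MotifDiscovery, GO
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'synthetic-data.R'
    'timecourse-io.R'
    'normalization.R'
    'cycling-detection.R'
    'phase-shift.R'
    'element-discovery.R'
    'go-tod.R'
    'sample-similarity.R'
    'pipeline.R'
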