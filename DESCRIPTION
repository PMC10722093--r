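Package: markerforge
Title: Genome-Wide InDel, CAPS and Amplicon-SNP Marker Design from
    Multi-Sample VCF Genotyping Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers variant sites that distinguish two sample groups in a
    multi-sample VCF and designs validated PCR markers against the reference
    genome: InDel markers scored by product-length difference, CAPS (cleaved
    amplified polymorphic sequence) markers scored by differential restriction
    digestion, and tagged amplicon-SNP markers for multiplex PCR target
    amplicon sequencing. Candidate loci are screened by sample grouping and
    marker-type rules, design templates are masked for nearby segregating
    variants and low read depth, primers are designed with a nearest-neighbor
    thermodynamic engine, checked genome-wide for off-target facing pairs,
    filtered for hairpins and primer dimers, and iteratively redesigned.
    Includes restriction-site scanning with IUPAC degeneracy, digestion
    fragment prediction, multiplex panel filtering and spacing, and a seeded
    synthetic-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Genetics, SNP, Sequencing, VariantAnnotation, Software
RoxygenNote: 7.3.3
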