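Package: gencurate
Title: Contig Screening, Annotation Curation and 3' UTR Extension for
    Draft Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly computations for draft rodent genome projects:
    taxonomic adjudication of contaminant-flagged contigs by summed BLAST
    bitscores with an order-level retention rule, a five-rule deterministic
    curation pipeline for homology-predicted gene annotations (gene-name
    resolution, named-locus deduplication, cross-gene shared-exon removal,
    short-exon and splice-consensus filtering, identical-isoform
    deduplication), a distance-gated constant 3' UTR extension with read
    assignment delta metrics, assembly contiguity statistics (thresholded
    counts, N50/L50) and BUSCO short-summary arithmetic validation. Seeded
    synthetic-fixture generators with planted-truth ledgers make every
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
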