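Package: draftpatch
Title: Reference-Guided Draft Genome Patching, Liftover and Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for improving a gapped draft genome with a set of
    higher-quality contigs: finds N-run gaps and computes assembly statistics
    (contig counts, N50, gap totals), turns contig-to-draft alignments into a
    non-overlapping patch plan, applies replacements and spanned-gap fills,
    emits UCSC-style coordinate chains, substitutes filtered variant calls
    into the patched sequence, lifts gene annotations through the chains and
    classifies transcripts whose gaps were completely filled, validates
    clone-end (BAC-end) pair placements by chromosome, orientation and insert
    size, and computes LD-pruned allele-sharing distances with classical
    scaling (PCoA) for population structure. A seeded simulator generates
    truth genomes, gapped drafts, patch-ready contigs, annotations, clone-end
    pairs, pileups and structured genotype matrices so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    vcfR,
    dplyr,
    tibble,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
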