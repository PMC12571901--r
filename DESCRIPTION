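Package: asodesignr
Title: Antisense Oligomer Design and Knockdown Screen Analysis for Phage
    Functional Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of short antisense oligomers (peptide
    nucleic acids) that silence bacteriophage genes by blocking translation
    initiation, together with the analytics used in phage knockdown screens.
    Extracts strand-corrected translation-initiation-region windows from
    annotated phage and host genomes (FASTA+GFF3 or GenBank), enumerates and
    scores candidate 11-mer antisense sequences (nearest-neighbor duplex
    melting temperature with a peptide-nucleic-acid correction, purine
    fraction, self-complementarity), counts mismatch-tolerant off-target
    sites across all translation initiation regions, builds tiling sets and
    central-mismatch negative controls, converts serial-dilution spot counts
    into colony/plaque titers and ordinal effect categories, classifies
    transcripts into early versus middle/late temporal classes from
    differential-expression tables, and generates seeded synthetic genomes,
    spot-count tables and expression tables with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    ggplot2,
    generics,
    IRanges,
    purrr,
    S4Vectors,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
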