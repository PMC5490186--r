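Package: svase
Title: Sequence Variants Associated with Splicing Events from RNA-seq Split Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies sequence variants (DNA mutations or RNA-editing events)
    that are statistically associated with specific RNA splicing events, using
    only junction-spanning split reads from a spliced RNA-seq alignment.
    Splice junctions are discovered from CIGAR N operations, filtered by read
    depth and a background-expression Fisher exact test over related junctions
    (those sharing a donor or acceptor), and each junction is decomposed into
    independent donor-side and acceptor-side parts for de novo variant calling
    restricted to its supporting reads. Candidate variants pass count, allele
    fraction and Fisher significance gates, an allele-frequency consistency
    check against related junctions, and a variant-junction association test
    before being reported. Also provides junction-shift (alignment ambiguity)
    detection against known introns, donor/acceptor splice-signal scoring with
    a trainable position weight matrix, known-site source-type annotation,
    VCF/BED/TSV/FASTA output, summary tables and plots, and a deterministic
    synthetic-data generator with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
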