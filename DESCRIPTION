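Package: mobsv
Title: Insertion-Sequence Transposition and Large Deletion Calling from
    Paired-End Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects large (>200 bp) structural variants in resequenced
    bacterial genomes from the paired-end signal alone: insertion-sequence
    (IS) transposition events are located as genome windows with a
    Poisson-unexpected excess of one-end-anchored ("unpaired") read pairs,
    and large deletions as clusters of read pairs whose apparent insert
    size is shifted upward relative to a robust insert-size model. Includes
    a synthetic mobilome simulator (multi-replicon genome, IS catalog with
    terminal inverted repeats and target-site duplications, paired-end
    reads, ideal alignments) so the whole pipeline is testable without
    external data or an aligner, and a gene-annotation layer producing a
    per-mutation report (gene, product, inserted element).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
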