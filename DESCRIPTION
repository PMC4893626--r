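Package: homeoexpr
Title: Homoeologue Expression Analysis in Allopolyploid Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for global and homoeologue-specific gene
    expression in interspecific hybrids and allopolyploids, built around
    read-count RNA-seq data from two diploid parents, a diploid F1 hybrid
    and a later-generation allotetraploid.  Provides Fisher's-exact-test
    differential expression on pooled read counts with RPKM normalization
    and Benjamini-Hochberg correction, the twelve-category classification
    of expression level dominance, diagnostic-SNP homoeologue read
    binning from SAM alignments, homoeologue expression bias state
    transitions, silencing and novel-expression calling at a
    reads-per-million threshold, mid-parent-value trajectory partitioning
    of expression changes into genome-merger and genome-doubling effects,
    and homoeologue-specific qPCR quantification by the 2^-ddCt method.
    A negative-binomial synthetic-data generator with recorded ground
    truth supports end-to-end validation without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
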