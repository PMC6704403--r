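Package: lncsieve
Title: Discovery of Intergenic Long Non-Coding RNAs from Assembled Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate long non-coding RNAs (lncRNAs) in assembled
    transcriptomes through a three-part pipeline: a gradient-boosted decision
    tree classifier operating on 21 intrinsic sequence features (ORF structure,
    Fickett TESTCODE statistic, hexamer usage bias, nucleotide composition),
    a genomic-overlap sieve that removes UTR fragments and transcripts sharing
    loci with protein-coding genes, pseudogenes or structural non-coding RNAs,
    and an SPM (specificity measure) module that scores tissue specificity of
    expression and calls transcripts preferentially expressed in one or both
    olfactory organs. A synthetic-data generator produces sequence corpora,
    toy genome annotations and expression matrices with known ground truth so
    the whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    xgboost,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
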