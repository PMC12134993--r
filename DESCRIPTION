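Package: tandemtag
Title: Design and In-Silico Cloning of Tandem Epitope-Tag Multimers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico construct-design and cloning-simulation toolkit for
    iterative epitope-tag multimerization. Designs synthesis-ready 5X tandem
    epitope-tag seed plasmids flanked by AscI/XhoI and SalI/NotI sites,
    simulates the digest/ligate doubling rounds that produce 10X, 20X, 40X
    and 80X multimers with full reading-frame and restriction-site
    bookkeeping, predicts diagnostic restriction digests, and designs
    conditional knock-in donor sequences (C-terminal tag fusion plus a
    recombinase-flanked STOP cassette in an intron, with PAM mutations in the
    homology arms and sequence-level excision simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    yaml,
    withr,
    utils,
    tools,
    stats
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
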