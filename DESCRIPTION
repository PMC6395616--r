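Package: paleofrac
Title: Subgenome Reconstruction and Fractionation Analysis After
    Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the two paleo-subgenomes of a genome that
    experienced a recent whole-genome duplication, using a closely related
    diploid outgroup, and quantifies fractionation bias, evolutionary-rate
    bias, homeolog expression dominance and DNA-methylation bias between
    the subgenomes and between singleton and homeologous genes. Includes
    dynamic-programming synteny chaining with block-level false-positive
    filters, NG86 Ka/Ks estimation with Jukes-Cantor correction, Gaussian
    mixture dating of block Ks distributions, sliding-window gene-retention
    profiling, TPM-based expression dominance classification, weighted
    metagene methylation profiling, and a fully labelled synthetic-data
    generator so that every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
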