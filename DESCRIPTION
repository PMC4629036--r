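Package: refasm
Title: Reference-Assisted Assembly of Closely Related Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs the genome of an organism that is closely related
    (around one percent divergence) to an available reference genome, directly
    from the experimental sequencing reads. Low-quality pseudoreads tiled from
    the reference are co-assembled with the experimental reads by a
    quality-aware de Bruijn micro-assembler (or any external assembler), the
    resulting contigs are mapped back to the reference, and the best-scoring
    contigs are spliced into the reference to produce an "edited reference"
    that is closer to the sequenced genome while retaining full genome
    coverage. Includes the standard assembly-quality metric suite (total
    length, N50, length-weighted percent identity, identical bases, fold
    coverage), a genome-evolution simulator and a paired-end read simulator so
    the whole pipeline can be exercised on synthetic data, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
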