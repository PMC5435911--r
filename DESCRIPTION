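Package: circmito
Title: Circularized RNA Sequencing Analysis for Circular Organellar Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the 5' and 3' termini of individual RNAs from
    paired-end sequencing of circularized, rolling-circle reverse-transcribed
    molecules aligned to a small circular genome. Provides a ground-truth
    library simulator emulating intramolecular RNA circularization, RNase R
    selection, rolling-circle cDNA synthesis and 250 bp paired-end sequencing;
    adapter trimming and read-pair overlap merging; tandem-repeat detection
    and consensus monomer collapsing; a seed-and-extend soft-clipping aligner
    for circular genomes with end-to-end realignment of clipped read parts;
    junction ("link") calling that infers original molecule termini, with
    CPM-normalized end profiles, coverage and log2 fold-change tracks between
    conditions; and small-RNA extraction with 3'-CCA and non-templated
    poly(A) tail classification and per-gene replicate statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
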