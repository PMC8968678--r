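Package: OligoTiler
Title: Melting-Temperature-Uniform Oligonucleotide Design for Gene Synthesis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Designs oligodeoxynucleotide sets for gene synthesis by ligase
    chain reaction or assembly PCR. A three-stage procedure divides an input
    gene into overlap segments of near-uniform duplex melting temperature:
    a greedy segmentation over a 20-30 bp overlap-length band, an iterative
    boundary-refinement stage that minimises the standard deviation of the
    overlap melting-temperature profile, and a Viterbi-style dynamic program
    over end-shrunk candidate segments that produces gapped-assembly designs.
    Melting temperatures come from the unified nearest-neighbor
    thermodynamic parameter set with salt, strand-concentration and
    phosphate-count corrections. Oligo sets are emitted as FASTA, a TSV
    report and BED tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    BiocGenerics,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Alignment, SyntheticBiology
RoxygenNote: 7.3.3
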