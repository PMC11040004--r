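Package: kedit
Title: Kinetoplast Genome Annotation and U-Indel RNA Editing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the mitochondrial (kinetoplast) genomes of
    trypanosomatid flagellates: structural annotation of minicircles and
    maxicircles (conserved sequence blocks, inverted repeats, guide-RNA genes),
    antiparallel gRNA:mRNA duplex alignment with Watson-Crick and G:U wobble
    pairing, T-stripped read alignment for uridine insertion/deletion editing,
    edited open-reading-frame reconstruction, 3'-to-5' editing-cascade
    reconstruction, non-cognate guiding attribution, mitochondrial codon-usage
    and targeting-signal analyses, and a ground-truthed synthetic kinetoplast
    data generator for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
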