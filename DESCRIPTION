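Package: cubtools
Title: Codon Usage Bias Analysis for Nuclear and Organellar Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the classical codon-usage-bias workflow on
    protein-coding sequences: CDS quality control, per-gene usage indices
    (RSCU, Wright's effective number of codons, positional GC content,
    synonymous third-base composition), ENC-plot, PR2-plot and
    neutrality-plot diagnostics of mutation versus selection, optimal-codon
    determination from ENC-extreme gene groups via delta-RSCU, association
    of codon bias with gene expression at the sequence, codon and
    amino-acid levels, and RSCU-based genome clustering with Newick export.
    Includes a synthetic CDS and expression generator with known bias
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
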