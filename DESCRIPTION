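Package: ychrom
Title: Y-Chromosome Linkage Assignment, Indel Repair Signatures, Copy
    Number, and Gene-Conversion Bounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the structural evolution of Drosophila Y
    chromosomes from short-read depth and sequence alignments. Assigns
    assembly contigs to the Y chromosome from male versus female per-base
    read depth with window-level validation; extracts insertions and
    deletions from duplicate-versus-parent alignments, measures breakpoint
    microhomology, and classifies the likely double-strand-break repair
    mechanism (non-homologous end joining, microhomology-mediated end
    joining, or replication slippage); filters population indel
    polymorphism from VCF files and compares indel size spectra across
    chromosome classes; estimates per-exon copy number of Y-linked genes
    from depth normalized by the modal single-copy depth; and bounds
    gene-conversion activity among ampliconic gene copies with four-gamete
    tests and the Hudson-Kaplan minimum number of recombination events.
    A synthetic-data generator with known ground truth supports validation
    of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
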