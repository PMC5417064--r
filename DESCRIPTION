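Package: informativity
Title: Informativity Scoring of Homology Hits for Taxon Detection in Viral Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies, for each annotated gene of a viral taxon of interest, how
    reliably a homology hit to that gene indicates the taxon's presence in a
    sequenced community. A per-gene taxonomic signal threshold is computed by
    comparing each gene to within-taxon relative genomes (most dissimilar
    homolog) and to an out-group reference (best hit); metagenomic contigs are
    six-frame translated and their hits are scored against the threshold to
    yield an informativity value, separating genes that mark the taxon from
    genes shared across taxa through lateral gene transfer. Includes a seeded
    synthetic phage-community simulator with planted lateral transfers for
    end-to-end validation, a BLAST tabular interface, and TSV/heatmap-matrix
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    methods,
    graphics,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
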