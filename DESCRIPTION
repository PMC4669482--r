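Package: allotetra
Title: Subgenome Assignment and Genome Dynamics in Allotetraploid Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing allotetraploid genome assemblies built from two
    diverged parental genomes (an A-like and a D-like progenitor). Assigns
    assembly scaffolds to parental subgenomes from progenitor shotgun-read
    coverage using a three-criteria classifier (covered fraction, log2 coverage
    ratio, Student's t-test across replicate libraries), detects inter-subgenome
    hybrid scaffolds and projects their junctions onto a reference, anchors
    scaffolds into pseudochromosomes from a genetic map of 201-bp SNP segments,
    dates LTR retrotransposon insertions from 5'/3' terminal-repeat divergence
    under the Kimura two-parameter model, partitions lineage-specific SNPs from
    multi-sample VCFs, and classifies homoeologous gene-pair expression bias
    from FPKM matrices. A synthetic-tetraploid generator with full ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    methods,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
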