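Package: swingerome
Title: Systematic Genome Transformations, Expanded-Codon Translation and
    Non-Canonical Peptide Enrichment Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing non-canonical mitochondrial translation.
    Generates the 23 bijective nucleotide-exchange ("swinger")
    transformations and the nine systematic-deletion ("del")
    transformations of a genome with exact coordinate maps, translates
    transformed sequences along tri-, tetra- and pentacodons in all frames
    of both strands under the vertebrate mitochondrial genetic code, builds
    non-redundant in-silico tryptic peptide databases with 19-fold stop
    expansion, and implements the enrichment statistics applied to detected
    peptide populations: terminal-residue bias tables, chi-square
    enrichment tests, Fisher p-value combination, one-tailed Pearson
    correlation, peptide-on-RNA mapping enrichment, nuclear-code
    compatibility expectations and a spectrum cross-correlation utility.
    Includes a synthetic-data generator for detection tables and RNA
    coverage tracks so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, Genetics, SequenceMatching, StatisticalMethod
RoxygenNote: 7.3.3
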