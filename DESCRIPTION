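Package: prmlamin
Title: Targeted PRM Assay Design and Quantification for Lamin A Proteoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and evaluation of parallel reaction monitoring (PRM)
    assays that discriminate lamin A proteoforms: mature lamin A,
    farnesylated prelamin A, and farnesylated progerin, the permanently
    farnesylated lamin A variant that accumulates in Hutchinson-Gilford
    progeria syndrome. Provides monoisotopic mass and m/z calculus for
    peptides carrying noncanonical modifications (C-terminal farnesyl and
    O-methyl cysteine, carbamidomethyl cysteine, 13C/15N heavy labels),
    derivation of proteoforms from prelamin A processing rules, in silico
    tryptic digestion and signature-peptide selection, transition-table
    design with farnesyl neutral-loss and MS3 traces, extracted ion
    chromatogram (XIC) integration with relative (internal-control
    normalised) and absolute (stable-isotope dilution) quantification, and
    a seeded synthetic PRM-run generator with mzML export so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
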