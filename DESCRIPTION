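Package: qtysol
Title: QTY-Code Solubilization Analysis of Membrane Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and evaluate water-soluble QTY analogs of
    alpha-helical membrane proteins. Applies the QTY substitution code
    (L to Q, I and V to T, F to Y) inside annotated transmembrane segments,
    computes sequence characteristics (variation percentages, molecular
    weight, isoelectric point), superposes predicted analog structures onto
    experimental references with loop-trimmed C-alpha Kabsch fits, quantifies
    hydrophobic solvent-accessible surface before and after substitution, and
    scores protein-protein interface preservation across multi-chain
    complexes with DockQ (Fnat, LRMS, iRMS, CAPRI classes). Includes a
    deterministic synthetic-data generator for annotated transmembrane
    sequences, ideal helices and perturbed toy complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
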