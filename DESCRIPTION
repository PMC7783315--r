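Package: cepstruct
Title: Structural Analysis Toolkit for the Lactococcal Cell-Envelope Proteinase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating full-length structural models of
    the Lactococcus lactis cell-envelope proteinase (PrtP/CEP) from per-segment
    predictions: stitching overlapping residue-residue contact maps into a
    full-length composite, detecting domain boundaries and tandem-repeat
    periodicity from contact density, rigid-body (Kabsch) superposition with
    RMSD and TM-score for model-ensemble comparison and medoid reference
    selection, catalytic-triad geometry measurement and assembled/displaced
    state classification, residue coordinate-scheme mapping between ORF and
    mature numbering, naive axial domain assembly, and a synthetic-fixture
    generator with known ground truth for end-to-end testing. Includes a
    pipeline driver and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
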