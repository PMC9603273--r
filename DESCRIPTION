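Package: opxtools
Title: Classification of Outer-Membrane Polysaccharide Export Proteins and
    Cell-Envelope Geometry from Cryo-Electron Tomography Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying bacterial outer-membrane polysaccharide export
    (OPX) proteins. Parses HMMER3 per-domain tables and fold-recognition
    homology regions, assembles ordered protein domain architectures, and
    assigns each protein to one of three OPX structural classes (Wza-like
    Class 1, GfcC-containing Class 2A-D, truncated Class 3) from combined
    sequence- and fold-level evidence. Scans gene neighborhoods for syntenic
    beta-barrel porin homologues by local alignment, extracts the Poly_export
    domain as a phylogenetic marker with tree-annotation layers, and measures
    periplasm thickness between inner- and outer-membrane polyline traces
    from tomographic slices, including correlation of thickness with OPX
    protein length. A synthetic-data module generates every input with
    planted ground truth so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
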