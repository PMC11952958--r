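Package: saxlink
Title: Integrative SAXS, Cross-Linking MS and Variant-Depletion Analysis of
    Protein Oligomerization on Double-Stranded RNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the integrative structural analysis of protein complexes
    that compact and oligomerize along double-stranded RNA. Implements SEC-SAXS
    reduction and solution analysis (Guinier fitting, regularized indirect
    Fourier transform for the pair-distance distribution P(r) and D_max,
    dimensionless Kratky transforms, volume-of-correlation molecular-weight
    estimation, Debye theoretical curves from coordinates, and sparse
    multi-state ensemble fitting), quantitative cross-linking mass-spectrometry
    fold-change classification with structure-based Calpha-Calpha distance
    validation under crystallographic symmetry expansion, per-domain missense
    variant depletion statistics (Vd/Vp), mass-photometry stoichiometry
    assignment, steric footprint inference on duplex RNA, lateral oligomer
    model building with clash checks, and bead-on-string particle statistics.
    A synthetic-data module provides seeded generators with ground-truth
    records for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    mclust,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
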