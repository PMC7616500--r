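Package: stitchkit
Title: Stitching, Doublet Consolidation and Spatial Statistics for Visium Limb Atlases
Version: 0.1.0
Authors@R: person("Atlas", "Tools", email = "atlas.tools@example.org", role = c("aut", "cre"))
Description: Toolkit for multi-capture-area Visium section stitching via
    6-coefficient planar affine transforms with a centre-priority image
    compositing rule, cluster-consolidated doublet flagging using a
    median/MAD normal null with Benjamini-Hochberg correction, RNA-ISH
    pixel co-occurrence probabilities from binary expression masks,
    odds-ratio selection of axis-biased genes from non-zero cell
    fractions, NMF-based microenvironment membership, scRNA-seq quality
    control filters and crown-rump-length embryonic age estimation.
    Includes seeded synthetic-data generators so the full pipeline is
    testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
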