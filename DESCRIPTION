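Package: C2Cartographer
Title: Structure-Based Cartography of C2 Beta-Sandwich Domains
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping C2 beta-sandwich domains in protein coordinate
    models. Assigns backbone hydrogen bonds with the Kabsch-Sander electrostatic
    model, chains beta-bridges into ladders, strands and sheets, recognizes
    eight-stranded C2 beta-sandwiches, classifies their strand connectivity
    (Type-I versus Type-II circular permutants), extracts domain boundaries from
    the hydrogen-bond pattern of the first and eighth strands, names the three
    calcium-binding-pocket apex loops, detects loop insertions relative to a
    reference domain and calls conserved subdomains across paralogs. Includes
    rigid-body Kabsch superposition, overlapping-fragment stitching, sequence
    analytics (composition, isoelectric point, molar extinction coefficient,
    transmembrane-span arithmetic, hydropathy scans) and a deterministic
    synthetic beta-sandwich generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
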