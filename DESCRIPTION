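Package: g4geom
Title: Geometric Annotation of G-Quadruplex Structures and Their Bulges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the geometric analysis of left- and right-handed
    G-quadruplex (G4) nucleic-acid structures from atomic coordinates:
    detection of Hoogsteen-bonded G-tetrads, assembly of the tetrad core
    into G-columns and stacked blocks, helical handedness classification
    from signed stacking twists, classification of non-core nucleotides
    as bulges, loops, linkers or overhangs, backbone and glycosidic
    torsion profiling, sugar pucker analysis (pseudorotation phase angle
    and z-deviation), least-squares superposition RMSDs, and comparison
    of transition dihedral angles around bulges against reference
    profiles built from non-bulged structures. Includes a deterministic
    generator of idealized G4 coordinate models so every stage of the
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
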