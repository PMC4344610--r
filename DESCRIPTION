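Package: glycotorsion
Title: Conformational Analysis of Glycosidic Linkages Against NMR Observables
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of glycosidic-linkage conformational ensembles from
    molecular simulations or synthetic models, validated against solution
    NMR. Computes ensemble-averaged trans-glycosidic 3J(C-H) coupling
    constants through a Karplus relation, relative NOE intensities through
    reciprocal averaged r^-6 interproton distances, conformer populations
    on the phi/psi torus, and dihedral-driving conformational energy maps.
    Ships the experimental coupling and NOE tables for five fucosylated
    chondroitin sulfate oligosaccharide fragments as packaged data, a
    wrapped-Gaussian mixture generator of torsional and Cartesian
    ensembles, and readers for multi-MODEL PDB, multi-frame XYZ and
    torsion-table inputs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
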