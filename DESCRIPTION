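Package: rgcnet
Title: Equivariant Vector-Scalar Message-Passing Neural Network Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Machine-learned interatomic potentials built on runtime geometry
    calculation: per-atom direction units whose inner products and vector
    rejections encode sums of bond-angle, dihedral-torsion and improper-angle
    cosines in time linear in the number of edges.  Provides the geometry
    primitives with explicit enumeration oracles, a real spherical-harmonics
    extension via the addition theorem, an equivariant vector-scalar
    message-passing network with energy-conserving analytic forces obtained by
    reverse-mode differentiation, combined energy/force training, a minimal
    velocity-Verlet/Berendsen molecular-dynamics driver with interatomic
    distance-distribution analysis, and a synthetic-data module of analytic
    bonded toy potentials used as exact oracles throughout the test suite.
    Reads and writes multi-frame extended-XYZ files and MD17-style compressed
    array archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
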