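Package: excitOT
Title: Optimal-Transport Diagnostics for Electronic Excitation Character
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies molecular electronic excitations (local,
    charge-transfer, Rydberg) from volumetric orbital data using
    entropic optimal transport. Implements a log-domain Sinkhorn solver
    with a separable squared-Euclidean kernel on regular 3D grids, the
    debiased Sinkhorn divergence, the transport diagnostic Theta and its
    variance-normalized dimensionless form, the orbital-overlap Lambda
    diagnostic, difference-density descriptors (D_CT),
    attachment/detachment density analysis with the phi_S overlap, and a
    k-nearest-neighbor excitation classifier with confusion-matrix
    evaluation. Reads and writes Gaussian cube files and ships a
    synthetic Gaussian-density generator so the whole pipeline is
    testable without any electronic-structure calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
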