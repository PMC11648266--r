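Package: ionplan
Title: Multi-Model RBE-Weighted Fluence Optimization for Scanned Carbon-Ion Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse treatment planning for scanned carbon-ion beams in which
    dose objectives for each region of interest can be expressed in several
    relative biological effectiveness (RBE) models simultaneously. Provides an
    analytic pencil-beam dose/LET fixture on synthetic voxel phantoms, mixed-field
    linear-quadratic biology with per-model alpha/beta tables and clinical dose
    scaling, sparse dose-influence assembly, a projected-gradient fluence
    optimizer supporting single-model, mixed-RBE and multi-RBE scenarios, and
    dose-volume-histogram plan evaluation (D_x%, D_2cc, V_D, homogeneity index,
    median-dose scaling factor) with clinical goal checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    RNifti,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
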