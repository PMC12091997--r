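Package: mesocoat
Title: Quantitative Analysis of Mesoscale Protein Coats on Bacterial Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing guanylate-binding protein (GBP1) coat
    complexes assembled on Gram-negative bacteria: molecule census from
    volumetric imaging with fluorescence-enhancement correction, van der Waals
    packing volumes and maximal extents from atomic coordinates, cooperative
    (Hill) assembly-kinetics fitting, equilibrium LPS-binding isotherm fitting
    from fluorescence anisotropy, cryo-ET conformer length metrology and
    surface-density enumeration, Fourier shell correlation resolution
    estimation, disulfide cross-link candidate screening by C-beta distances,
    and seeded synthetic-data generators emulating every input so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
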