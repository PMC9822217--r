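Package: bonemapr
Title: Patient-Specific Bone Material Mapping from CT for Finite-Element Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns patient-specific elastic properties to tetrahedral
    finite-element bone models from calibrated CT. Provides a CT volume data
    model with trilinear Hounsfield-unit (HU) interpolation, readers for
    NIfTI, raw-plus-sidecar and uncompressed DICOM series, an Abaqus/VTK
    tet4 mesh layer, configurable HU-to-density-to-modulus law chains
    (calibration lines, density conversions, piecewise power laws), three
    element HU-averaging strategies (node average, interior-voxel average,
    volume integration), material binning into element sets with
    volume-fraction distributions, deterministic synthetic phantoms, and a
    small linear-elastic tet4 verification solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
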