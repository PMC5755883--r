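Package: aneuflow
Title: Hemodynamic Quantification of Intracranial Aneurysm Flow Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intra-aneurysmal hemodynamics from time-resolved
    three-component voxel velocity fields such as 4D phase-contrast MRI
    reconstructions or resampled CFD solutions. Computes average sac velocity at
    the systolic peak, intra-aneurysmal kinetic energy, planar recirculation from
    the vorticity field, wall shear stress and its sac-normalized distribution,
    and pre/post flow-diverter relative reductions. Includes analytic pulsatile
    flow phantoms (Poiseuille tube, sac vortex) with closed-form ground truth,
    PC-MRI-like degradation (velocity-encoding wrap, Gaussian component noise),
    and NIfTI/STL/CSV/JSON input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
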