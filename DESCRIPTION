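Package: pvesim
Title: Partial Volume Effect Simulation for Spherical Objects in CT
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the partial volume effect (PVE) that corrupts
    threshold-based size measurements of small spherical objects in computed
    tomography. A sphere of radius r (in units of the isotropic voxel edge k)
    is placed at random positions inside the central voxel of a cubic grid;
    every voxel is classified as inside, outside or cut by the sphere surface,
    the sphere-voxel intersection volume of each cut voxel is estimated by
    subdivision sampling (default 125 points per voxel), and the mixed
    Hounsfield-unit density of each cut voxel is compared against a
    segmentation cutoff to obtain the threshold-measured volume. Monte-Carlo
    averaging over sphere positions yields the measured-to-true volume ratio
    for clinical scenarios such as lung nodules in air and kidney stones in
    renal parenchyma, and an accuracy window analysis for Agatston calcium
    scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
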