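Package: CardioPhantom
Title: Synthetic Cine Cardiac MR Images with Exact Functional Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of short-axis balanced steady-state free
    precession (bSSFP) cine cardiac MR images paired with exact ground truth
    of left-ventricular morphology and function. A generative low-rank shape
    model produces healthy, dilated, hypertrophic and infarcted left
    ventricles; a reduced-order continuum-mechanics model (Holzapfel-Ogden
    passive law, active fiber stress, pericardial constraint) coupled to a
    lumped-parameter systemic circulation simulates one cardiac cycle; the
    moving ventricle is voxelized into multi-class label maps, embedded in a
    procedural torso by contour-matched warping, textured with PD/T1/T2
    tissue properties, and imaged with a closed-form bSSFP signal model,
    coil sensitivities, Cartesian k-space encoding and complex noise.
    Ground-truth masks, displacement fields, strain curves, volumes, mass
    and ejection fraction are packaged per frame, together with the
    evaluation metrics (Dice, displacement error, strain summaries) needed
    to benchmark segmentation and motion-estimation methods.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, grDevices, utils, igraph, jsonlite, yaml, RNifti
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
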