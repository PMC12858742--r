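Package: synthretarget
Title: Scenario-Targeted Synthetic Human Scenes with Exact Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Procedural generation of synthetic images of humans in bed-centric
    clinical scenes, with exact COCO-style ground truth (bounding boxes, 17
    keypoints, 3D joints), plus the detection-evaluation and paired-statistics
    machinery needed to quantify how much scenario-targeted synthetic training
    data improves human detection. Includes a parametric articulated humanoid
    with forward kinematics and axis-angle poses, heightfield blanket draping
    for occlusion, scenario presets for camera and lighting domain
    randomisation, a built-in z-buffered Lambertian rasterizer behind a
    renderer-agnostic interface, background compositing anchored to bed
    regions, COCO JSON reading/writing with leakage-guarded splits, AP/AR/OKS
    and per-person IoU scoring, and paired t / Wilcoxon / bootstrap analyses
    with Bonferroni control.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
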