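Package: BoneFrame
Title: Body-Coordinate Morphometry, Reconstruction and Sesamoid-Groove
    Analysis of Foot Bone Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inertial body-coordinate analysis of closed
    triangular surface meshes of individual bones. Computes mass
    properties (volume, surface area, centre of mass, inertia tensor)
    by divergence-theorem integration, builds principal-axes-of-inertia
    body frames, standardizes bone sets to a common metatarsal length,
    tabulates and normalizes linear and volumetric morphometrics,
    selects a best-matching donor subject, completes damaged bones from
    a donor mesh by voxel-domain overlap, and quantifies the sesamoid
    grooves of the first metatarsal head via rotating cross-sections,
    least-squares circle fitting of curvature diameters, and a groove
    parallelism test. Includes a parametric generator of bone-like test
    solids with carved cylindrical grooves and a damage operator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
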