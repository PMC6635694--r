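#' BoneMesh: a closed triangular bone surface
#'
#' Holds a triangular surface mesh of a single bone with coordinates in
#' millimetres. Face indices are 1-based rows into the vertex matrix.
#' Use [boneMesh()] to construct (it validates and repairs orientation)
#' and [readMesh()] to load from STL/PLY/OBJ.
#'
#' @slot vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @slot faces integer matrix, m x 3, vertex indices per triangle.
#' @slot name free-text label for the bone.
#' @slot units fixed to \code{"mm"}.
#' @exportClass BoneMesh
setClass("BoneMesh",
  representation(vertices = "matrix", faces = "matrix",
                 name = "character", units = "character"),
  prototype(name = "", units = "mm"))

setValidity("BoneMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  msg <- character()
  if (ncol(v) != 3) msg <- c(msg, "vertices must have 3 columns")
  if (ncol(f) != 3) msg <- c(msg, "faces must have 3 columns")
  if (nrow(v) == 0 || nrow(f) == 0) msg <- c(msg, "mesh is empty")
  if (length(msg) == 0) {
    if (any(f < 1) || any(f > nrow(v)))
      msg <- c(msg, "face indices out of range")
    if (any(f != round(f))) msg <- c(msg, "face indices must be integral")
  }
  if (!identical(object@units, "mm")) msg <- c(msg, "units must be 'mm'")
  if (length(msg)) msg else TRUE
})

#' MassProperties: volume, area, centre of mass and inertia of a solid
#'
#' Mass properties of the uniform-density solid enclosed by a watertight
#' [BoneMesh-class], computed by signed-tetrahedron (divergence-theorem)
#' integration with density fixed at 1.
#'
#' @slot volume enclosed volume (mm^3).
#' @slot surfaceArea total surface area (mm^2).
#' @slot com centre of mass, length-3 (mm).
#' @slot inertia symmetric 3 x 3 inertia tensor about the COM, unit
#'   density (mm^5).
#' @exportClass MassProperties
setClass("MassProperties",
  representation(volume = "numeric", surfaceArea = "numeric",
                 com = "numeric", inertia = "matrix"))

setValidity("MassProperties", function(object) {
  msg <- character()
  if (object@volume <= 0) msg <- c(msg, "volume must be > 0")
  if (object@surfaceArea <= 0) msg <- c(msg, "surface area must be > 0")
  if (length(object@com) != 3) msg <- c(msg, "com must have length 3")
  I <- object@inertia
  if (!all(dim(I) == c(3, 3))) msg <- c(msg, "inertia must be 3 x 3")
  else {
    if (max(abs(I - t(I))) > 1e-6 * max(abs(I)))
      msg <- c(msg, "inertia must be symmetric")
    ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
    if (ev[1] <= 0) msg <- c(msg, "inertia must be positive definite")
    # principal moments obey the triangle-type inequality for real solids
    if (ev[3] > ev[1] + ev[2] + 1e-6 * ev[3])
      msg <- c(msg, "principal moments violate Ix <= Iy + Iz")
  }
  if (length(msg)) msg else TRUE
})

#' BodyFrame: inertial body coordinate system of a bone
#'
#' Origin at the centre of mass, axes along the principal axes of
#' inertia, ordered ascending by principal moment so the first axis is
#' the elongation ("long") axis. Axes are stored as rows of a
#' right-handed orthonormal matrix.
#'
#' @slot origin centre of mass (mm).
#' @slot axes 3 x 3 orthonormal matrix; row i is the i-th body axis.
#' @slot handedness +1 (right-handed).
#' @slot moments the three principal moments (ascending, mm^5).
#' @slot degenerate TRUE when near-equal moments forced the fallback
#'   axis ordering.
#' @exportClass BodyFrame
setClass("BodyFrame",
  representation(origin = "numeric", axes = "matrix",
                 handedness = "numeric", moments = "numeric",
                 degenerate = "logical"),
  prototype(handedness = 1, degenerate = FALSE))

setValidity("BodyFrame", function(object) {
  msg <- character()
  A <- object@axes
  if (!all(dim(A) == c(3, 3))) return("axes must be 3 x 3")
  if (max(abs(A %*% t(A) - diag(3))) > 1e-9)
    msg <- c(msg, "axes must be orthonormal")
  if (det(A) < 0) msg <- c(msg, "axes must be right-handed")
  if (length(object@origin) != 3) msg <- c(msg, "origin must have length 3")
  if (length(msg)) msg else TRUE
})

#' StandardizedSet: a subject's three bones at metatarsal length 100
#'
#' The three bones of a subject's first metatarsophalangeal joint
#' (first metatarsal, proximal phalanx, distal phalanx), each in its own
#' body frame, uniformly scaled so the metatarsal's body-frame length is
#' exactly 100.
#'
#' @slot metatarsal,proximal,distal [BoneMesh-class] objects in body
#'   frames, post-scaling.
#' @slot scale the dimensionless uniform scale factor that was applied.
#' @slot originalLengths named length-3 vector of pre-scaling body-frame
#'   lengths (mm).
#' @exportClass StandardizedSet
setClass("StandardizedSet",
  representation(metatarsal = "BoneMesh", proximal = "BoneMesh",
                 distal = "BoneMesh", scale = "numeric",
                 originalLengths = "numeric"))

#' RatioTable: morphometric ratios against a reference subject
#'
#' Per-(subject, bone, measure) ratios of measurement values to those of
#' a reference subject, as used to rank donor candidates. The reference
#' row is identically 1.
#'
#' @slot reference the reference subject's label.
#' @slot data long-format data.frame with columns subject, bone,
#'   measure, value, ratio (full precision).
#' @slot measures character vector of measure names, in column order.
#' @exportClass RatioTable
setClass("RatioTable",
  representation(reference = "character", data = "data.frame",
                 measures = "character"))

setValidity("RatioTable", function(object) {
  msg <- character()
  need <- c("subject", "bone", "measure", "value", "ratio")
  if (!all(need %in% names(object@data)))
    msg <- c(msg, "data must have subject/bone/measure/value/ratio")
  else {
    if (any(object@data$ratio <= 0)) msg <- c(msg, "ratios must be > 0")
    ref <- object@data[object@data$subject == object@reference, "ratio"]
    if (length(ref) == 0) msg <- c(msg, "reference subject absent")
    else if (max(abs(ref - 1)) > 1e-12)
      msg <- c(msg, "reference row must be identically 1")
  }
  if (length(msg)) msg else TRUE
})

#' CrossSection: planar section of a bone mesh
#'
#' Intersection of a mesh with a plane, as one or more closed planar
#' contours expressed in 2D in-plane coordinates (mm). The in-plane
#' basis is (\code{axisU}, \code{axisV}): \code{axisV} is the section's
#' rotation axis and \code{axisU} completes the right-handed triplet
#' (axisU, axisV, normal).
#'
#' @slot planePoint,planeNormal the section plane (mm / unit vector).
#' @slot axisU,axisV in-plane unit basis vectors (3D).
#' @slot contours list of k x 2 matrices of closed contours (last point
#'   not repeated).
#' @slot area total enclosed area (mm^2), holes subtracted.
#' @exportClass CrossSection
setClass("CrossSection",
  representation(planePoint = "numeric", planeNormal = "numeric",
                 axisU = "numeric", axisV = "numeric",
                 contours = "list", area = "numeric"))

setValidity("CrossSection", function(object) {
  if (object@area < 0) return("area must be >= 0")
  if (!length(object@contours)) return("section has no contours")
  TRUE
})

#' GrooveFit: fitted curvature circle of a sesamoid groove
#'
#' Result of scanning rotated cross-sections of the first metatarsal
#' head and fitting a least-squares circle to one groove's concave arc.
#' The curvature diameter (CD) is twice the fitted radius; the rotation
#' angle is signed, negative meaning clockwise when viewed from the
#' positive rotation-axis direction.
#'
#' @slot side \code{"medial"} or \code{"lateral"}.
#' @slot rotationAngle signed scan angle (degrees) at the reported fit.
#' @slot circleCenter 2D centre in section coordinates (mm).
#' @slot curvatureDiameter fitted CD (mm).
#' @slot rmsResidual root-mean-square radial residual (mm).
#' @slot arcPoints number of contour points in the fitted arc.
#' @slot trace data.frame with one row per scanned angle (angle, cd,
#'   rms, npts) for inspection.
#' @slot settings list of scan settings (axis, pivot, step, range,
#'   objective) used; compared by [parallelismTest()].
#' @exportClass GrooveFit
setClass("GrooveFit",
  representation(side = "character", rotationAngle = "numeric",
                 circleCenter = "numeric", curvatureDiameter = "numeric",
                 rmsResidual = "numeric", arcPoints = "integer",
                 trace = "data.frame", settings = "list"),
  prototype(trace = data.frame(), settings = list()))

setValidity("GrooveFit", function(object) {
  msg <- character()
  if (!object@side %in% c("medial", "lateral"))
    msg <- c(msg, "side must be 'medial' or 'lateral'")
  if (object@curvatureDiameter <= 0) msg <- c(msg, "CD must be > 0")
  if (object@rmsResidual < 0) msg <- c(msg, "rms residual must be >= 0")
  if (object@arcPoints < 5L) msg <- c(msg, "arc must have >= 5 points")
  if (length(msg)) msg else TRUE
})

#' ParallelismResult: same-section parallelism verdict for the grooves
#'
#' Compares the scan angles at which the medial and lateral grooves
#' attain their minimal curvature diameter. The grooves are parallel
#' when both minima occur in the same cross-section, i.e. the absolute
#' angle difference is within tolerance.
#'
#' @slot medialFit,lateralFit the two [GrooveFit-class] objects.
#' @slot angleDifference medial minus lateral rotation angle (degrees).
#' @slot verdict \code{"parallel"} or \code{"dis_parallel"}.
#' @slot tolerance angular tolerance (degrees).
#' @exportClass ParallelismResult
setClass("ParallelismResult",
  representation(medialFit = "GrooveFit", lateralFit = "GrooveFit",
                 angleDifference = "numeric", verdict = "character",
                 tolerance = "numeric"))

setValidity("ParallelismResult", function(object) {
  ok <- (abs(object@angleDifference) <= object@tolerance) ==
    (object@verdict == "parallel")
  if (!ok) return("verdict inconsistent with angle difference/tolerance")
  TRUE
})

#' DefectReport: result of completing a damaged bone from a donor
#'
#' @slot completed the watertight completed [BoneMesh-class].
#' @slot boundaryLoops number of open boundary loops detected on the
#'   damaged input surface.
#' @slot boundaryLength total open boundary edge length (mm).
#' @slot defectFraction fraction (0-1) of the donor surface area used
#'   for patching.
#' @slot patchArea donor surface area flagged as missing (mm^2).
#' @exportClass DefectReport
setClass("DefectReport",
  representation(completed = "BoneMesh", boundaryLoops = "integer",
                 boundaryLength = "numeric", defectFraction = "numeric",
                 patchArea = "numeric"))

setValidity("DefectReport", function(object) {
  if (object@defectFraction < 0 || object@defectFraction > 1)
    return("defectFraction must be in [0, 1]")
  TRUE
})

#' BoneParams: parameters of the synthetic bone generator
#'
#' Parametric description of a bone-like solid: a superellipsoid shaft
#' capped by a spherical head into which two cylindrical sesamoid
#' grooves of known radii and axis orientations are carved on the
#' plantar side. Groove skew angles are rotations of the groove axis
#' about the vertical body axis, in degrees; 0 means the groove runs
#' along the bone's long axis.
#'
#' @slot shaftLength,shaftRadii,headRadius shaft length, the two shaft
#'   semi-radii (width, height) and head radius, mm.
#' @slot grooveRadiusMedial,grooveRadiusLateral groove radii (mm).
#' @slot grooveSkewMedial,grooveSkewLateral groove axis skew (degrees).
#' @slot grooveDepthFrac carve depth as a fraction of groove radius.
#' @slot groovePolarAngle angular position of each groove axis from the
#'   plantar direction, degrees.
#' @slot meshResolution subdivision level; voxel pitch is
#'   headRadius / (10 * meshResolution).
#' @slot bumpAmplitude relative amplitude of seeded low-frequency
#'   surface bumps (0 disables).
#' @slot seed integer seed for the bump field.
#' @exportClass BoneParams
setClass("BoneParams",
  representation(shaftLength = "numeric", shaftRadii = "numeric",
                 headRadius = "numeric",
                 grooveRadiusMedial = "numeric",
                 grooveRadiusLateral = "numeric",
                 grooveSkewMedial = "numeric",
                 grooveSkewLateral = "numeric",
                 grooveDepthFrac = "numeric",
                 groovePolarAngle = "numeric",
                 meshResolution = "numeric",
                 bumpAmplitude = "numeric", seed = "numeric"))

setValidity("BoneParams", function(object) {
  msg <- character()
  if (object@shaftLength <= 0 || any(object@shaftRadii <= 0) ||
      object@headRadius <= 0)
    msg <- c(msg, "all dimensions must be > 0")
  if (length(object@shaftRadii) != 2)
    msg <- c(msg, "shaftRadii must have length 2")
  if (object@grooveRadiusMedial >= object@headRadius ||
      object@grooveRadiusLateral >= object@headRadius)
    msg <- c(msg, "groove radii must be smaller than the head radius")
  if (object@meshResolution < 2) msg <- c(msg, "meshResolution must be >= 2")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: known properties of a generated synthetic bone
#'
#' @slot volume,surfaceArea oracle values from the generator's voxel
#'   grid and output mesh (mm^3, mm^2).
#' @slot grooveCD named vector, true curvature diameter (2 x radius)
#'   per side (mm).
#' @slot grooveAngles named vector, true groove axis skew per side
#'   (degrees).
#' @slot damageFraction removed-volume fraction if a damage operator
#'   was applied, else 0.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(volume = "numeric", surfaceArea = "numeric",
                 grooveCD = "numeric", grooveAngles = "numeric",
                 damageFraction = "numeric"),
  prototype(damageFraction = 0))
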