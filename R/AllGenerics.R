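# Generics and simple accessors / show methods.

#' @describeIn BoneMesh-class vertex coordinate matrix (n x 3, mm)
#' @param object,x a BoneMesh
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @export
setMethod("vertices", "BoneMesh", function(x) x@vertices)

#' @describeIn BoneMesh-class face index matrix (m x 3, 1-based)
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @export
setMethod("faces", "BoneMesh", function(x) x@faces)

#' @describeIn BoneMesh-class the bone's label
#' @export
setGeneric("meshName", function(x) standardGeneric("meshName"))
#' @export
setMethod("meshName", "BoneMesh", function(x) x@name)

#' Volume of a solid
#' @param x an object with a volume (MassProperties, BoneMesh, ...)
#' @return volume in mm^3
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))
#' @export
setMethod("volume", "MassProperties", function(x) x@volume)
#' @export
setMethod("volume", "BoneMesh", function(x) massProperties(x)@volume)

#' Surface area
#' @param x a MassProperties or BoneMesh
#' @return area in mm^2
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))
#' @export
setMethod("surfaceArea", "MassProperties", function(x) x@surfaceArea)
#' @export
setMethod("surfaceArea", "BoneMesh", function(x) triangleAreaTotal(x))

#' Centre of mass
#' @param x a MassProperties or BoneMesh
#' @return length-3 numeric, mm
#' @export
setGeneric("centerOfMass", function(x) standardGeneric("centerOfMass"))
#' @export
setMethod("centerOfMass", "MassProperties", function(x) x@com)
#' @export
setMethod("centerOfMass", "BoneMesh", function(x) massProperties(x)@com)

#' Inertia tensor about the centre of mass (unit density)
#' @param x a MassProperties
#' @return symmetric 3 x 3 matrix, mm^5
#' @export
setGeneric("inertiaTensor", function(x) standardGeneric("inertiaTensor"))
#' @export
setMethod("inertiaTensor", "MassProperties", function(x) x@inertia)

#' Principal moments of inertia (ascending)
#' @param x a MassProperties or BodyFrame
#' @return length-3 numeric, mm^5
#' @export
setGeneric("principalMoments", function(x) standardGeneric("principalMoments"))
#' @export
setMethod("principalMoments", "MassProperties", function(x)
  sort(eigen(x@inertia, symmetric = TRUE, only.values = TRUE)$values))
#' @export
setMethod("principalMoments", "BodyFrame", function(x) x@moments)

#' @describeIn BodyFrame-class frame origin (the COM)
#' @param x a BodyFrame
#' @export
setGeneric("frameOrigin", function(x) standardGeneric("frameOrigin"))
#' @export
setMethod("frameOrigin", "BodyFrame", function(x) x@origin)

#' @describeIn BodyFrame-class 3 x 3 matrix with body axes as rows
#' @export
setGeneric("frameAxes", function(x) standardGeneric("frameAxes"))
#' @export
setMethod("frameAxes", "BodyFrame", function(x) x@axes)

#' @describeIn CrossSection-class list of closed 2D contours
#' @param x a CrossSection
#' @export
setGeneric("contours", function(x) standardGeneric("contours"))
#' @export
setMethod("contours", "CrossSection", function(x) x@contours)

#' @describeIn CrossSection-class enclosed area (mm^2)
#' @export
setGeneric("sectionArea", function(x) standardGeneric("sectionArea"))
#' @export
setMethod("sectionArea", "CrossSection", function(x) x@area)

#' @describeIn GrooveFit-class fitted curvature diameter (mm)
#' @param x a GrooveFit
#' @export
setGeneric("curvatureDiameter", function(x) standardGeneric("curvatureDiameter"))
#' @export
setMethod("curvatureDiameter", "GrooveFit", function(x) x@curvatureDiameter)

#' @describeIn GrooveFit-class signed rotation angle of the fit (degrees)
#' @export
setGeneric("rotationAngle", function(x) standardGeneric("rotationAngle"))
#' @export
setMethod("rotationAngle", "GrooveFit", function(x) x@rotationAngle)

#' @describeIn ParallelismResult-class the parallel / dis_parallel verdict
#' @param x a ParallelismResult
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @export
setMethod("verdict", "ParallelismResult", function(x) x@verdict)

#' @describeIn ParallelismResult-class medial minus lateral angle (degrees)
#' @export
setGeneric("angleDifference", function(x) standardGeneric("angleDifference"))
#' @export
setMethod("angleDifference", "ParallelismResult", function(x) x@angleDifference)

#' @describeIn DefectReport-class the completed watertight mesh
#' @param x a DefectReport
#' @export
setGeneric("completedMesh", function(x) standardGeneric("completedMesh"))
#' @export
setMethod("completedMesh", "DefectReport", function(x) x@completed)

setMethod("show", "BoneMesh", function(object) {
  cat(sprintf("BoneMesh '%s': %d vertices, %d faces [%s]%s\n",
              object@name, nrow(object@vertices), nrow(object@faces),
              object@units,
              if (isWatertight(object)) ", watertight" else ", OPEN"))
})

setMethod("show", "MassProperties", function(object) {
  cat(sprintf("MassProperties: V = %.3f mm^3, A = %.3f mm^2\n",
              object@volume, object@surfaceArea))
  cat(sprintf("  COM = (%.3f, %.3f, %.3f) mm\n",
              object@com[1], object@com[2], object@com[3]))
  pm <- principalMoments(object)
  cat(sprintf("  principal moments = %.4g, %.4g, %.4g mm^5\n",
              pm[1], pm[2], pm[3]))
})

setMethod("show", "BodyFrame", function(object) {
  cat("BodyFrame (origin = COM, axes = principal axes of inertia)\n")
  cat(sprintf("  origin: (%.3f, %.3f, %.3f) mm%s\n", object@origin[1],
              object@origin[2], object@origin[3],
              if (object@degenerate) "  [degenerate fallback]" else ""))
  ax <- c("long", "second", "third")
  for (i in 1:3)
    cat(sprintf("  %-6s axis: (%+.4f, %+.4f, %+.4f), moment %.4g\n",
                ax[i], object@axes[i, 1], object@axes[i, 2],
                object@axes[i, 3], object@moments[i]))
})

setMethod("show", "StandardizedSet", function(object) {
  cat(sprintf("StandardizedSet: scale = %.6f (metatarsal length -> 100)\n",
              object@scale))
  cat(sprintf("  original lengths (mm): metatarsal %.3f, proximal %.3f, distal %.3f\n",
              object@originalLengths[1], object@originalLengths[2],
              object@originalLengths[3]))
})

setMethod("show", "RatioTable", function(object) {
  subj <- unique(object@data$subject)
  cat(sprintf("RatioTable: %d subjects x %d measures, reference '%s'\n",
              length(subj), length(object@measures), object@reference))
})

setMethod("show", "CrossSection", function(object) {
  cat(sprintf("CrossSection: %d contour(s), area %.3f mm^2\n",
              length(object@contours), object@area))
})

setMethod("show", "GrooveFit", function(object) {
  cat(sprintf("GrooveFit [%s]: CD = %.3f mm at rotation %+.2f deg (rms %.4f mm, %d pts)\n",
              object@side, object@curvatureDiameter, object@rotationAngle,
              object@rmsResidual, object@arcPoints))
})

setMethod("show", "ParallelismResult", function(object) {
  cat(sprintf("ParallelismResult: %s (|angle difference| = %.2f deg, tolerance %.2f deg)\n",
              object@verdict, abs(object@angleDifference), object@tolerance))
})

setMethod("show", "DefectReport", function(object) {
  cat(sprintf("DefectReport: %d boundary loop(s), %.2f mm boundary, patch %.2f mm^2 (%.1f%% of donor)\n",
              object@boundaryLoops, object@boundaryLength, object@patchArea,
              100 * object@defectFraction))
})
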