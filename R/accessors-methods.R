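#' Accessors for Volume objects
#'
#' @param x A \linkS4class{Volume}.
#' @return \code{volData}: the 3D array; \code{spacing}, \code{origin}:
#'   numeric length-3 vectors in mm; \code{direction}: 3x3 matrix;
#'   \code{spaceName}: character tag.
#' @name volumeAccessors
NULL

#' @rdname volumeAccessors
#' @export
setMethod("volData", "Volume", function(x) x@data)
#' @rdname volumeAccessors
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)
#' @rdname volumeAccessors
#' @export
setMethod("origin", "Volume", function(x) x@origin)
#' @rdname volumeAccessors
#' @export
setMethod("direction", "Volume", function(x) x@direction)
#' @rdname volumeAccessors
#' @export
setMethod("spaceName", "Volume", function(x) x@spaceName)
#' @rdname volumeAccessors
#' @export
setMethod("dim", "Volume", function(x) dim(x@data))

#' Accessors for SectionImage objects
#'
#' @param x A \linkS4class{SectionImage}.
#' @return \code{pixelSize}: mm per pixel; \code{sectionIndex}: zero-based
#'   integer; \code{sectionKind}: character; \code{volData}: the pixel array.
#' @name sectionAccessors
NULL

#' @rdname sectionAccessors
#' @export
setMethod("pixelSize", "SectionImage", function(x) x@pixelSize)
#' @rdname sectionAccessors
#' @export
setMethod("sectionIndex", "SectionImage", function(x) x@sectionIndex)
#' @rdname sectionAccessors
#' @export
setMethod("sectionKind", "SectionImage", function(x) x@kind)
#' @rdname sectionAccessors
#' @export
setMethod("volData", "SectionImage", function(x) x@data)

#' Accessors for landmark containers
#'
#' @param x A \linkS4class{LandmarkSet} or \linkS4class{PairedLandmarks}.
#' @return \code{pointCoords}: n x d matrix (mm); \code{pointLabels}:
#'   character labels; \code{dimensionality}: 2 or 3; \code{sourceSet} /
#'   \code{targetSet}: the member \linkS4class{LandmarkSet}s of a pair.
#' @name landmarkAccessors
NULL

#' @rdname landmarkAccessors
#' @export
setMethod("pointCoords", "LandmarkSet", function(x) x@coords)
#' @rdname landmarkAccessors
#' @export
setMethod("pointLabels", "LandmarkSet", function(x) rownames(x@coords))
#' @rdname landmarkAccessors
#' @export
setMethod("dimensionality", "LandmarkSet", function(x) ncol(x@coords))
#' @rdname landmarkAccessors
#' @export
setMethod("spaceName", "LandmarkSet", function(x) x@spaceName)
#' @rdname landmarkAccessors
#' @export
setMethod("length", "LandmarkSet", function(x) nrow(x@coords))
#' @rdname landmarkAccessors
#' @export
setMethod("sourceSet", "PairedLandmarks", function(x) x@source)
#' @rdname landmarkAccessors
#' @export
setMethod("targetSet", "PairedLandmarks", function(x) x@target)
#' @rdname landmarkAccessors
#' @export
setMethod("length", "PairedLandmarks", function(x) nrow(x@source@coords))
#' @rdname landmarkAccessors
#' @export
setMethod("dimensionality", "PairedLandmarks",
          function(x) ncol(x@source@coords))

#' Accessors for RigidTransform objects
#'
#' @param x A \linkS4class{RigidTransform}.
#' @return \code{rotation}: 3x3 proper rotation matrix; \code{translation}:
#'   length-3 vector in mm.
#' @name rigidAccessors
NULL

#' @rdname rigidAccessors
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)
#' @rdname rigidAccessors
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)
#' @rdname rigidAccessors
#' @export
setMethod("rotation", "RigidFitReport", function(x) x@transform@rotation)
#' @rdname rigidAccessors
#' @export
setMethod("translation", "RigidFitReport", function(x) x@transform@translation)

#' Accessors for ParametricMapStack objects
#'
#' @param x A \linkS4class{ParametricMapStack}.
#' @return \code{mapChannels}: named list of \linkS4class{Volume}s;
#'   \code{roiMask}: the ROI label \linkS4class{Volume};
#'   \code{channelUnits}: named character vector of units.
#' @name stackAccessors
NULL

#' @rdname stackAccessors
#' @export
setMethod("mapChannels", "ParametricMapStack", function(x) x@channels)
#' @rdname stackAccessors
#' @export
setMethod("roiMask", "ParametricMapStack", function(x) x@roi)
#' @rdname stackAccessors
#' @export
setMethod("channelUnits", "ParametricMapStack", function(x) x@units)

## show methods ---------------------------------------------------------------

setMethod("show", "Volume", function(object) {
  cat(sprintf("Volume '%s': %s voxels, spacing (%s) mm\n",
              object@spaceName, paste(dim(object@data), collapse = " x "),
              paste(format(object@spacing), collapse = ", ")))
  cat(sprintf("  origin (%s) mm\n",
              paste(format(object@origin, digits = 4), collapse = ", ")))
})

setMethod("show", "SectionImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("SectionImage (%s) #%d: %d x %d px at %.4g mm/px (%.4g x %.4g mm)\n",
              object@kind, object@sectionIndex, d[1], d[2], object@pixelSize,
              d[1] * object@pixelSize, d[2] * object@pixelSize))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet '%s': %d points (%dD)\n", object@spaceName,
              nrow(object@coords), ncol(object@coords)))
})

setMethod("show", "PairedLandmarks", function(object) {
  cat(sprintf("PairedLandmarks: %d pairs (%dD), '%s' -> '%s'\n",
              nrow(object@source@coords), ncol(object@source@coords),
              object@source@spaceName, object@target@spaceName))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%s) mm\n",
              ang * 180 / pi,
              paste(format(object@translation, digits = 4), collapse = ", ")))
})

setMethod("show", "RigidFitReport", function(object) {
  cat(sprintf("RigidFitReport: %d landmarks, rms residual %.4g mm\n",
              object@nLandmarks, object@rmsResidual))
  show(object@transform)
})

setMethod("show", "TPSWarp", function(object) {
  cat(sprintf("TPSWarp: %d control points, lambda = %g\n",
              nrow(object@controlSource), object@lambda))
})

setMethod("show", "ParametricMapStack", function(object) {
  cat(sprintf("ParametricMapStack: %s grid, %d ROI voxels\n",
              paste(dim(object@roi@data), collapse = " x "),
              sum(object@roi@data > 0)))
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "PlateAngles", function(object) {
  cat(sprintf("PlateAngles: elevation %.4f deg, azimuth %.4f deg, in-plane %.4f deg\n",
              object@elevation, object@azimuth, object@inPlane))
})

setMethod("show", "SlicePlan", function(object) {
  cat(sprintf("SlicePlan: %d slices along axis %d, spacing %g mm (%g to %g mm)\n",
              length(object@positions), object@axis, object@spacing,
              min(object@positions), max(object@positions)))
})

setMethod("show", "TREResult", function(object) {
  cat(sprintf("TREResult [%s / %s / %s]: %d distances over %d iterations (median %.3f mm)\n",
              object@pairKind, object@sectionLevel, object@patientId,
              length(object@distances), object@nIterations,
              stats::median(object@distances)))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k = %d, %d ROI voxels, inertia %.4g\n",
              object@k, sum(object@labels@data > 0), object@inertia))
})
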