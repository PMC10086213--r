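## Accessor generics. Slot access from user code is discouraged; these are the
## supported surface.

#' @rdname volumeAccessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname volumeAccessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname volumeAccessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname volumeAccessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @rdname volumeAccessors
#' @export
setGeneric("spaceName", function(x) standardGeneric("spaceName"))

#' @rdname sectionAccessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname sectionAccessors
#' @export
setGeneric("sectionIndex", function(x) standardGeneric("sectionIndex"))
#' @rdname sectionAccessors
#' @export
setGeneric("sectionKind", function(x) standardGeneric("sectionKind"))

#' @rdname landmarkAccessors
#' @export
setGeneric("pointCoords", function(x) standardGeneric("pointCoords"))
#' @rdname landmarkAccessors
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))
#' @rdname landmarkAccessors
#' @export
setGeneric("dimensionality", function(x) standardGeneric("dimensionality"))
#' @rdname landmarkAccessors
#' @export
setGeneric("sourceSet", function(x) standardGeneric("sourceSet"))
#' @rdname landmarkAccessors
#' @export
setGeneric("targetSet", function(x) standardGeneric("targetSet"))

#' @rdname rigidAccessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname rigidAccessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname stackAccessors
#' @export
setGeneric("mapChannels", function(x) standardGeneric("mapChannels"))
#' @rdname stackAccessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname stackAccessors
#' @export
setGeneric("channelUnits", function(x) standardGeneric("channelUnits"))

#' Apply a rigid transform
#'
#' Maps landmark coordinates \eqn{p \to R p + t}, or resamples a volume onto
#' a fixed grid so that the transformed image is expressed in the fixed
#' space (linear interpolation for scalar volumes, nearest-neighbour for
#' label volumes; out-of-field voxels are 0).
#'
#' @param transform A \linkS4class{RigidTransform}.
#' @param x A \linkS4class{LandmarkSet} (3D) or \linkS4class{Volume}.
#' @param ... Further arguments passed to methods: for volumes,
#'   \code{reference} (target-grid \linkS4class{Volume}, default the input
#'   grid) and \code{interpolation} (\code{"linear"} or \code{"nearest"}).
#' @return An object of the same class as \code{x}.
#' @export
setGeneric("applyRigid", function(transform, x, ...) standardGeneric("applyRigid"))
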