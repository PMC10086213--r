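#' @import methods
NULL

.ORTHO_TOL <- 1e-6

#' Canonical parametric channel names
#'
#' The eight co-registered quantitative MRI channels used throughout the
#' package, in fixed order: diffusion (ADC), intravoxel-incoherent-motion
#' (Dstar, f, fDstar) and dynamic contrast-enhanced pharmacokinetic
#' (Ktrans, kep, ve, vp) parameters.
#'
#' @return Character vector of the eight channel names.
#' @export
channelNames <- function() {
  c("ADC", "Dstar", "f", "fDstar", "Ktrans", "kep", "ve", "vp")
}

## Alternate spellings accepted on read; "iAUC" is the initial area under the
## enhancement curve, accepted as the fourth DCE channel in place of vp.
.channelAliases <- c(
  "D*" = "Dstar", "DSTAR" = "Dstar", "fD*" = "fDstar", "FDSTAR" = "fDstar",
  "iAUC" = "vp", "IAUC" = "vp", "KTRANS" = "Ktrans", "KEP" = "kep",
  "VE" = "ve", "VP" = "vp", "adc" = "ADC"
)

.canonicalChannel <- function(x) {
  out <- x
  hit <- x %in% names(.channelAliases)
  out[hit] <- .channelAliases[x[hit]]
  out
}

.is_orthonormal <- function(m, tol = .ORTHO_TOL) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) &&
    max(abs(crossprod(m) - diag(3))) < tol
}

## ---------------------------------------------------------------------------
## Volume
## ---------------------------------------------------------------------------

#' Volume: a 3D scalar image with world geometry
#'
#' Carrier for in vivo and ex vivo MRI scans, ROI masks and label maps.
#' World coordinates follow NIfTI RAS semantics in millimetres: the world
#' position of zero-based voxel index \eqn{i} is
#' \eqn{origin + direction \cdot (spacing \circ i)}; voxel centres carry the
#' coordinates.
#'
#' @slot data 3D numeric array.
#' @slot spacing Per-axis voxel size in mm (length 3, strictly positive).
#' @slot origin World position (mm) of voxel index (0,0,0).
#' @slot direction 3x3 orthonormal matrix mapping index axes to world axes.
#' @slot spaceName Coordinate-space tag, e.g. \code{"in_vivo"},
#'   \code{"ex_vivo_1"}, \code{"ex_vivo_2"}.
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix", spaceName = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "expected 3D volume data")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be a finite 3-vector")
    if (!.is_orthonormal(object@direction))
      msg <- c(msg, "direction must be a 3x3 orthonormal matrix")
    if (length(object@spaceName) != 1L)
      msg <- c(msg, "spaceName must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Construct a Volume
#'
#' @param data 3D numeric array.
#' @param spacing Voxel size in mm, length 3 (recycled from length 1).
#' @param origin World position of voxel (0,0,0) in mm.
#' @param direction 3x3 orthonormal index-to-world direction matrix.
#' @param spaceName Coordinate-space tag.
#' @return A \linkS4class{Volume}.
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3), spaceName = "unnamed") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("Volume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction,
      spaceName = spaceName)
}

## ---------------------------------------------------------------------------
## SectionImage
## ---------------------------------------------------------------------------

.SECTION_KINDS <- c("macroscopic", "histology_HE", "histology_IHC")

#' SectionImage: a digitized 2D specimen section
#'
#' Holds a macroscopic photograph or a digitized stained microtomy section
#' with its physical pixel size and its position along the cutting axis.
#'
#' @slot data 2D matrix (grayscale) or h x w x 3 array (RGB), values in [0,1]
#'   for image files or arbitrary scalars for derived sections.
#' @slot pixelSize mm per pixel (> 0).
#' @slot sectionIndex Zero-based integer position along the cutting axis.
#' @slot kind One of \code{"macroscopic"}, \code{"histology_HE"},
#'   \code{"histology_IHC"}.
#' @export
setClass("SectionImage",
  representation(data = "array", pixelSize = "numeric",
                 sectionIndex = "integer", kind = "character"),
  validity = function(object) {
    msg <- character()
    nd <- length(dim(object@data))
    if (!(nd == 2L || (nd == 3L && dim(object@data)[3L] %in% c(1L, 3L))))
      msg <- c(msg, "data must be a 2D matrix or an h x w x {1,3} array")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive value (mm)")
    if (length(object@sectionIndex) != 1L || object@sectionIndex < 0L)
      msg <- c(msg, "sectionIndex must be a single non-negative integer")
    if (!object@kind %in% .SECTION_KINDS)
      msg <- c(msg, paste("kind must be one of:",
                          paste(.SECTION_KINDS, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct a SectionImage
#'
#' @param data 2D matrix or h x w x 3 array.
#' @param pixelSize mm per pixel.
#' @param sectionIndex Zero-based section position along the cutting axis.
#' @param kind Section kind (see \linkS4class{SectionImage}).
#' @return A \linkS4class{SectionImage}.
#' @export
SectionImage <- function(data, pixelSize, sectionIndex = 0L,
                         kind = "macroscopic") {
  if (is.matrix(data)) data <- array(data, dim = dim(data))
  new("SectionImage", data = data, pixelSize = as.numeric(pixelSize),
      sectionIndex = as.integer(sectionIndex), kind = kind)
}

## ---------------------------------------------------------------------------
## LandmarkSet / PairedLandmarks
## ---------------------------------------------------------------------------

#' LandmarkSet: labeled points in a named coordinate space
#'
#' @slot spaceName Coordinate-space tag.
#' @slot coords n x d numeric matrix (d = 2 or 3) in mm; row names are the
#'   unique landmark labels.
#' @export
setClass("LandmarkSet",
  representation(spaceName = "character", coords = "matrix"),
  validity = function(object) {
    msg <- character()
    d <- ncol(object@coords)
    if (!d %in% c(2L, 3L))
      msg <- c(msg, "coordinates must be 2D or 3D")
    if (is.null(rownames(object@coords)) ||
        anyDuplicated(rownames(object@coords)))
      msg <- c(msg, "landmark labels must be present and unique")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a LandmarkSet
#'
#' @param coords n x d numeric matrix (d = 2 or 3), coordinates in mm.
#' @param labels Unique labels, one per point; defaults to L01, L02, ...
#' @param spaceName Coordinate-space tag.
#' @return A \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(coords, labels = NULL, spaceName = "unnamed") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!is.null(labels)) {
    rownames(coords) <- labels
  } else if (is.null(rownames(coords))) {
    rownames(coords) <- sprintf("L%02d", seq_len(nrow(coords)))
  }
  new("LandmarkSet", spaceName = spaceName, coords = coords)
}

#' PairedLandmarks: matched correspondences between two spaces
#'
#' Source and target sets are matched by label; the constructor reorders the
#' target to the source's label order.
#'
#' @slot source,target \linkS4class{LandmarkSet}s with identical label sets
#'   and dimensionality.
#' @export
setClass("PairedLandmarks",
  representation(source = "LandmarkSet", target = "LandmarkSet"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@source@coords) != ncol(object@target@coords))
      msg <- c(msg, "source and target must share dimensionality")
    if (!identical(rownames(object@source@coords),
                   rownames(object@target@coords)))
      msg <- c(msg, "source and target must hold identical labels in identical order")
    if (length(msg)) msg else TRUE
  })

#' Construct PairedLandmarks
#'
#' @param source,target \linkS4class{LandmarkSet}s; target is reordered to
#'   match the source labels.
#' @return A \linkS4class{PairedLandmarks}.
#' @export
PairedLandmarks <- function(source, target) {
  lab <- rownames(source@coords)
  if (!setequal(lab, rownames(target@coords)))
    stop("source and target landmark label sets differ")
  tc <- target@coords[lab, , drop = FALSE]
  target2 <- new("LandmarkSet", spaceName = target@spaceName, coords = tc)
  new("PairedLandmarks", source = source, target = target2)
}

## ---------------------------------------------------------------------------
## RigidTransform
## ---------------------------------------------------------------------------

#' RigidTransform: proper rotation plus translation in mm
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation Length-3 translation vector in mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.is_orthonormal(object@rotation))
      msg <- c(msg, "rotation must be 3x3 orthonormal")
    else if (abs(det(object@rotation) - 1) > .ORTHO_TOL)
      msg <- c(msg, "improper rotation: determinant must be +1")
    if (length(object@translation) != 3L ||
        any(!is.finite(object@translation)))
      msg <- c(msg, "translation must be a finite 3-vector")
    if (length(msg)) msg else TRUE
  })

#' Construct a RigidTransform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 translation in mm.
#' @return A \linkS4class{RigidTransform}.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

## ---------------------------------------------------------------------------
## TPSWarp
## ---------------------------------------------------------------------------

#' TPSWarp: a 2D thin-plate-spline mapping
#'
#' Maps a point p (mm) to \code{c(1, p) \%*\% affine + sum_i w_i U(|p - c_i|)}
#' with kernel \eqn{U(r) = r^2 \log r}. At regularization 0 the warp
#' interpolates each control pair exactly; the kernel weights satisfy the
#' thin-plate side conditions (zero sum, orthogonal to the control
#' coordinates).
#'
#' @slot controlSource,controlTarget n x 2 control point matrices (mm).
#' @slot affine 3 x 2 affine coefficients (row 1 intercept, rows 2-3 linear).
#' @slot weights n x 2 kernel weights.
#' @slot lambda Regularization (>= 0).
#' @export
setClass("TPSWarp",
  representation(controlSource = "matrix", controlTarget = "matrix",
                 affine = "matrix", weights = "matrix", lambda = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@controlSource)
    if (ncol(object@controlSource) != 2L || ncol(object@controlTarget) != 2L)
      msg <- c(msg, "control points must be 2D")
    if (nrow(object@controlTarget) != n || nrow(object@weights) != n)
      msg <- c(msg, "control/weight row counts must agree")
    if (!all(dim(object@affine) == c(3L, 2L)))
      msg <- c(msg, "affine part must be 3x2")
    if (object@lambda < 0)
      msg <- c(msg, "lambda must be >= 0")
    if (n > 0) {
      side <- crossprod(cbind(1, object@controlSource), object@weights)
      if (max(abs(side)) > 1e-8 * max(1, max(abs(object@controlTarget))))
        msg <- c(msg, "kernel weights violate thin-plate side conditions")
    }
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## ParametricMapStack
## ---------------------------------------------------------------------------

#' ParametricMapStack: eight co-registered quantitative maps plus tumor ROI
#'
#' All channels and the ROI share one grid (shape, spacing, origin,
#' direction). The channel set is exactly the eight names of
#' \code{\link{channelNames}}; \code{"iAUC"} is accepted on construction as
#' an alternate name for the fourth DCE channel \code{vp}.
#'
#' @slot channels Named list of \linkS4class{Volume}s in canonical order.
#' @slot roi Label \linkS4class{Volume} (> 0 inside the tumor ROI).
#' @slot units Named character vector of per-channel units.
#' @export
setClass("ParametricMapStack",
  representation(channels = "list", roi = "Volume", units = "character"),
  validity = function(object) {
    msg <- character()
    want <- channelNames()
    if (!identical(names(object@channels), want))
      msg <- c(msg, paste("channels must be exactly:",
                          paste(want, collapse = ", ")))
    else {
      ref <- object@roi
      for (nm in want) {
        ch <- object@channels[[nm]]
        if (!is(ch, "Volume")) { msg <- c(msg, "channels must be Volumes"); break }
        if (!identical(dim(ch@data), dim(ref@data)) ||
            max(abs(ch@spacing - ref@spacing)) > 1e-9 ||
            max(abs(ch@origin - ref@origin)) > 1e-9 ||
            max(abs(ch@direction - ref@direction)) > 1e-9) {
          msg <- c(msg, sprintf("channel '%s' grid differs from ROI grid", nm))
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

.defaultUnits <- function() {
  c(ADC = "1e-3 mm^2/s", Dstar = "1e-3 mm^2/s", f = "%",
    fDstar = "1e-3 mm^2/s", Ktrans = "1/min", kep = "1/min",
    ve = "mL/mL", vp = "a.u.")
}

#' Construct a ParametricMapStack
#'
#' @param channels Named list of \linkS4class{Volume}s covering the eight
#'   canonical channels (aliases such as \code{"iAUC"} for \code{vp} and
#'   \code{"D*"} for \code{Dstar} are accepted).
#' @param roi Label \linkS4class{Volume} on the same grid.
#' @param units Optional named units; defaults to the conventional units of
#'   each parameter.
#' @return A \linkS4class{ParametricMapStack}.
#' @export
ParametricMapStack <- function(channels, roi, units = .defaultUnits()) {
  names(channels) <- .canonicalChannel(names(channels))
  if (!setequal(names(channels), channelNames()))
    stop("channels must cover exactly: ", paste(channelNames(), collapse = ", "),
         " (got: ", paste(names(channels), collapse = ", "), ")")
  channels <- channels[channelNames()]
  units <- units[channelNames()]
  new("ParametricMapStack", channels = channels, roi = roi, units = units)
}

## ---------------------------------------------------------------------------
## Planning / result containers
## ---------------------------------------------------------------------------

#' PlateAngles: angle-plate settings for agarose-block trimming
#'
#' @slot elevation Tilt of the plate normal from the vertical, degrees in
#'   [0, 180).
#' @slot azimuth Direction of the tilt in the horizontal plane, degrees
#'   counter-clockwise from world +x, in [-180, 180).
#' @slot inPlane Residual rotation about the plate normal, degrees in
#'   [-180, 180); reported but not needed for planar trimming.
#' @export
setClass("PlateAngles",
  representation(elevation = "numeric", azimuth = "numeric",
                 inPlane = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@elevation < 0 || object@elevation >= 180)
      msg <- c(msg, "elevation must lie in [0, 180)")
    if (object@azimuth < -180 || object@azimuth >= 180)
      msg <- c(msg, "azimuth must lie in [-180, 180)")
    if (object@inPlane < -180 || object@inPlane >= 180)
      msg <- c(msg, "inPlane must lie in [-180, 180)")
    if (length(msg)) msg else TRUE
  })

#' SlicePlan: sectioning positions on the 4 mm localizer grid
#'
#' @slot axis World/index axis of sectioning (1-3).
#' @slot positions Slice-centre offsets from the block face, mm, strictly
#'   increasing with constant spacing.
#' @slot spacing Slice spacing in mm (default 4 in \code{\link{planSlices}}).
#' @export
setClass("SlicePlan",
  representation(axis = "integer", positions = "numeric", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@spacing <= 0)
      msg <- c(msg, "spacing must be > 0")
    if (length(object@positions) > 1) {
      gaps <- diff(object@positions)
      if (any(gaps <= 0) || max(abs(gaps - object@spacing)) > 1e-9)
        msg <- c(msg, "positions must increase with constant spacing")
    }
    if (length(msg)) msg else TRUE
  })

#' RigidFitReport: result of a least-squares rigid fit
#'
#' @slot transform The fitted \linkS4class{RigidTransform} (moving to fixed).
#' @slot rmsResidual Root-mean-square residual in mm.
#' @slot nLandmarks Number of landmark pairs used (>= 3).
#' @export
setClass("RigidFitReport",
  representation(transform = "RigidTransform", rmsResidual = "numeric",
                 nLandmarks = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@rmsResidual < 0) msg <- c(msg, "rmsResidual must be >= 0")
    if (object@nLandmarks < 3L) msg <- c(msg, "nLandmarks must be >= 3")
    if (length(msg)) msg else TRUE
  })

#' TREResult: pooled target registration errors from the split protocol
#'
#' @slot pairKind One of \code{"histology_exvivo"}, \code{"histology_invivo"},
#'   \code{"exvivo_invivo"}.
#' @slot sectionLevel One of \code{"caudal"}, \code{"middle"},
#'   \code{"cranial"} (or \code{"unspecified"}).
#' @slot patientId Free-text identifier.
#' @slot distances Euclidean errors (mm) pooled over all iterations.
#' @slot iterationOf 1-based iteration index of each pooled distance.
#' @slot perIterationMedian Median error per iteration (mm).
#' @slot nIterations Number of random-split iterations completed.
#' @slot splitFraction Fraction of landmarks used for registration.
#' @slot seed RNG seed of the protocol run.
#' @slot nAborted Iterations aborted by fit failures.
#' @export
setClass("TREResult",
  representation(pairKind = "character", sectionLevel = "character",
                 patientId = "character", distances = "numeric",
                 iterationOf = "integer",
                 perIterationMedian = "numeric", nIterations = "integer",
                 splitFraction = "numeric", seed = "integer",
                 nAborted = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@distances < 0)) msg <- c(msg, "distances must be >= 0")
    if (object@splitFraction <= 0 || object@splitFraction >= 1)
      msg <- c(msg, "splitFraction must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' ClusterResult: voxel-wise habitat clustering of a parametric map stack
#'
#' @slot labels Label \linkS4class{Volume}: 0 outside the ROI, 1..k inside,
#'   renumbered by descending cluster size.
#' @slot k Number of clusters (>= 2).
#' @slot featureMeans k x 8 cluster centroids in standardized units.
#' @slot channelOrder The eight channel names.
#' @slot seed RNG seed.
#' @slot inertia Total within-cluster sum of squares.
#' @export
setClass("ClusterResult",
  representation(labels = "Volume", k = "integer", featureMeans = "matrix",
                 channelOrder = "character", seed = "integer",
                 inertia = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@k < 2L) msg <- c(msg, "k must be >= 2")
    lab <- object@labels@data
    if (any(lab < 0 | lab > object@k))
      msg <- c(msg, "labels must lie in 0..k")
    if (length(msg)) msg else TRUE
  })
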