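## Cutting-angle derivation and slice planning. The agarose block carrying
## the specimen is re-oriented on an angle plate so that slicing along
## horizontal (world-z) planes reproduces the in vivo axial planes; the
## required plate setting follows from a virtual back-rotation of the
## sectioning normal through the (angulation-corrected) rigid alignment.

#' Rodrigues' rotation of a vector about a unit axis
#'
#' Computes \eqn{v\cos\theta + (a \times v)\sin\theta +
#' a (a \cdot v)(1 - \cos\theta)} for unit axis a; preserves the norm of v.
#'
#' @param axis Unit 3-vector (|axis| = 1 within 1e-9).
#' @param angle Rotation angle in radians.
#' @param v 3-vector to rotate.
#' @return The rotated 3-vector.
#' @examples
#' rodriguesRotate(c(0, 0, 1), pi / 2, c(1, 0, 0))  # -> (0, 1, 0)
#' @export
rodriguesRotate <- function(axis, angle, v) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("rotation axis must be non-zero")
  if (abs(nrm - 1) > 1e-9) stop("rotation axis must be a unit vector")
  cs <- cos(angle); sn <- sin(angle)
  cross <- c(axis[2] * v[3] - axis[3] * v[2],
             axis[3] * v[1] - axis[1] * v[3],
             axis[1] * v[2] - axis[2] * v[1])
  v * cs + cross * sn + axis * sum(axis * v) * (1 - cs)
}

#' Angle between two unit vectors
#'
#' Computed as \code{2 asin(|a - b| / 2)}, which stays accurate down to
#' machine epsilon for nearly parallel vectors (unlike \code{acos} of the
#' dot product).
#'
#' @param a,b Unit 3-vectors.
#' @return Angle in radians.
#' @export
vectorAngle <- function(a, b) {
  2 * asin(min(1, sqrt(sum((a - b)^2)) / 2))
}

#' Rotation matrix from axis and angle
#'
#' Matrix form of the axis-angle rotation,
#' \eqn{I + \sin\theta K + (1-\cos\theta)K^2} with K the skew matrix of the
#' unit axis.
#'
#' @param axis Unit 3-vector.
#' @param angle Rotation angle in radians.
#' @return 3x3 proper rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angle) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("rotation axis must be non-zero")
  a <- axis / nrm
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Plate rotation implied by (elevation, azimuth), both in degrees:
## Rz(az) Ry(el) Rz(-az); maps world z onto
## (sin el cos az, sin el sin az, cos el).
.plateRotationMatrix <- function(elevationDeg, azimuthDeg) {
  el <- elevationDeg * pi / 180
  az <- azimuthDeg * pi / 180
  Rz <- rotationAboutAxis(c(0, 0, 1), az)
  Ry <- rotationAboutAxis(c(0, 1, 0), el)
  Rz %*% Ry %*% t(Rz)
}

#' Rigid transform realized by an angle-plate setting
#'
#' The rotation that tilts the horizontal plate by \code{elevation} about a
#' horizontal axis oriented by \code{azimuth}, optionally followed by the
#' in-plane rotation about the tilted normal. Applied to world z it yields
#' the plate normal.
#'
#' @param angles A \linkS4class{PlateAngles}.
#' @param includeInPlane If TRUE, include the in-plane rotation about the
#'   plate normal (not needed for planar trimming).
#' @return A \linkS4class{RigidTransform} with zero translation.
#' @export
plateRotation <- function(angles, includeInPlane = FALSE) {
  stopifnot(is(angles, "PlateAngles"))
  P <- .plateRotationMatrix(angles@elevation, angles@azimuth)
  if (includeInPlane) {
    n <- drop(P %*% c(0, 0, 1))
    P <- rotationAboutAxis(n, angles@inPlane * pi / 180) %*% P
  }
  RigidTransform(rotation = P, translation = c(0, 0, 0))
}

#' Derive angle-plate settings by virtual back-rotation
#'
#' Given the rigid alignment of the ex vivo scan to the in vivo scan (and an
#' optional angulation of the original in vivo acquisition), the sectioning
#' normal n is the back-rotated world z: \eqn{n = (R_{ang} R)^{-1} e_z}.
#' The elevation is the angle between n and world z, the azimuth the
#' direction of n's horizontal projection (counter-clockwise from +x), and
#' the in-plane angle the residual rotation about n. Tilting the plate by
#' (elevation, azimuth) maps world z onto n, so slicing the re-oriented
#' block along world-z planes reproduces the in vivo axial planes.
#'
#' At elevation 0 the azimuth is degenerate and reported as 0 by
#' convention; the in-plane angle is then the rotation about z.
#'
#' @param rigid \linkS4class{RigidTransform} aligning ex vivo (moving) to
#'   in vivo (fixed).
#' @param inVivoAngulation Optional \linkS4class{RigidTransform} describing
#'   an angulated in vivo acquisition; identity if NULL.
#' @return A \linkS4class{PlateAngles}.
#' @export
computePlateAngles <- function(rigid, inVivoAngulation = NULL) {
  stopifnot(is(rigid, "RigidTransform"))
  total <- if (is.null(inVivoAngulation)) rigid else
    composeRigid(inVivoAngulation, rigid)
  B <- t(total@rotation)  # back-rotation
  n <- drop(B %*% c(0, 0, 1))
  horiz <- sqrt(n[1]^2 + n[2]^2)
  ## atan2 form is numerically stable where n is near either pole
  elevation <- atan2(horiz, n[3]) * 180 / pi
  azimuth <- if (horiz < 1e-12) 0 else atan2(n[2], n[1]) * 180 / pi
  if (azimuth >= 180) azimuth <- azimuth - 360
  ## exact n == -z: the sectioning planes are unoriented, so the antipodal
  ## normal gives the same planes; report the degenerate (0, 0) setting
  if (elevation >= 180) { elevation <- 0; azimuth <- 0 }
  P <- .plateRotationMatrix(elevation, azimuth)
  resid <- t(P) %*% B
  inPlane <- atan2(resid[2, 1], resid[1, 1]) * 180 / pi
  if (inPlane >= 180) inPlane <- inPlane - 360
  if (inPlane < -180) inPlane <- inPlane + 360
  new("PlateAngles", elevation = elevation, azimuth = azimuth,
      inPlane = inPlane)
}

#' Plan equidistant sectioning positions across a block
#'
#' Slice centres are placed every \code{spacingMm} starting
#' \code{spacingMm/2} from the block face, mirroring the 4 mm measuring grid
#' of the sectioning localizer; the count is
#' \code{floor(extent / spacingMm)}.
#'
#' @param block \linkS4class{Volume} of the trimmed block.
#' @param spacingMm Slice spacing in mm (default 4).
#' @param axis Index axis of sectioning (default 3).
#' @return A \linkS4class{SlicePlan}.
#' @examples
#' blk <- Volume(array(0, c(10, 10, 40)), spacing = c(1, 1, 1))
#' planSlices(blk)  # 10 positions at 2, 6, ..., 38 mm
#' @export
planSlices <- function(block, spacingMm = 4, axis = 3L) {
  stopifnot(is(block, "Volume"))
  if (spacingMm <= 0) stop("slice spacing must be > 0")
  extent <- dim(block@data)[axis] * block@spacing[axis]
  if (extent < spacingMm)
    stop(sprintf("block extent (%.3g mm) smaller than slice spacing (%.3g mm)",
                 extent, spacingMm))
  nSlices <- floor(extent / spacingMm)
  positions <- spacingMm / 2 + spacingMm * (seq_len(nSlices) - 1)
  new("SlicePlan", axis = as.integer(axis), positions = positions,
      spacing = spacingMm)
}

#' Match a histology section to its MRI slice on the localizer grid
#'
#' The second ex vivo MRI is planned on the same 4 mm grid that drives the
#' cutting device, so section k corresponds directly to MRI slice k. The
#' MRI slice spacing along the sectioning axis must equal the plan spacing.
#'
#' @param section A \linkS4class{SectionImage} (its \code{sectionIndex}
#'   selects the plan position).
#' @param plan A \linkS4class{SlicePlan}.
#' @param mri The grid-planned MRI \linkS4class{Volume}.
#' @return A list with \code{slice} (1-based MRI slice index) and
#'   \code{positionMm} (slice-centre offset from the block face).
#' @export
matchSectionToSlice <- function(section, plan, mri) {
  stopifnot(is(section, "SectionImage"), is(plan, "SlicePlan"),
            is(mri, "Volume"))
  if (abs(mri@spacing[plan@axis] - plan@spacing) > 1e-6)
    stop(sprintf("grid/slice spacing mismatch: MRI %.6g mm vs plan %.6g mm",
                 mri@spacing[plan@axis], plan@spacing))
  k <- section@sectionIndex
  if (k < 0L || k >= length(plan@positions))
    stop("section index ", k, " outside the slice plan (0..",
         length(plan@positions) - 1L, ")")
  if (k + 1L > dim(mri@data)[plan@axis])
    stop("matched slice exceeds the MRI volume")
  list(slice = k + 1L, positionMm = plan@positions[k + 1L])
}

#' Serialize plate angles and slice plans
#'
#' Plate angles are written as JSON in degrees with 6 decimals; slice plans
#' as a TSV with one row per slice.
#'
#' @param angles A \linkS4class{PlateAngles}.
#' @param plan A \linkS4class{SlicePlan}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writePlateAngles <- function(angles, path) {
  jsonlite::write_json(
    list(elevation_deg = round(angles@elevation, 6),
         azimuth_deg = round(angles@azimuth, 6),
         in_plane_deg = round(angles@inPlane, 6)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePlateAngles
#' @export
writeSlicePlan <- function(plan, path) {
  df <- data.frame(slice = seq_along(plan@positions) - 1L,
                   axis = plan@axis, position_mm = plan@positions,
                   spacing_mm = plan@spacing)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
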