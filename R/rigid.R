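## Landmark-driven least-squares rigid alignment (rotation + translation, no
## scaling). This replaces a manual GUI alignment of the ex vivo scan to the
## in vivo scan with the closed-form SVD (Kabsch/Procrustes) solution, which
## is deterministic and exactly recoverable on noiseless correspondences.

#' Estimate a rigid transform from paired 3D landmarks
#'
#' Closed-form least-squares fit of rotation plus translation (no scaling)
#' mapping the moving (source) points onto the fixed (target) points:
#' centroids are removed, the rotation is the SVD polar factor of the
#' cross-covariance, and a reflective optimum is corrected to a proper
#' rotation by flipping the sign of the smallest singular vector.
#'
#' @param pairs \linkS4class{PairedLandmarks} with at least 3 non-collinear
#'   3D pairs; source is the moving space, target the fixed space.
#' @return A \linkS4class{RigidFitReport} holding the transform, the RMS
#'   residual in mm and the number of landmarks.
#' @examples
#' src <- LandmarkSet(matrix(rnorm(30), 10, 3))
#' tf  <- RigidTransform(rotationAboutAxis(c(0, 0, 1), pi / 2), c(5, 0, 0))
#' tgt <- applyRigid(tf, src)
#' fit <- estimateRigid(PairedLandmarks(src, tgt))
#' @export
estimateRigid <- function(pairs) {
  stopifnot(is(pairs, "PairedLandmarks"))
  X <- pairs@source@coords
  Y <- pairs@target@coords
  if (ncol(X) != 3L) stop("rigid estimation requires 3D landmarks")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 landmark pairs, got ", n)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  if (qr(Xc)$rank < 2L)
    stop("degenerate landmark configuration: points are collinear ",
         "(rank < 2 after centering)")
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - drop(R %*% cx)
  res <- sweep(X %*% t(R), 2L, t, "+") - Y
  rms <- sqrt(mean(rowSums(res^2)))
  new("RigidFitReport",
      transform = RigidTransform(rotation = R, translation = t),
      rmsResidual = rms, nLandmarks = as.integer(n))
}

#' @rdname applyRigid
#' @export
setMethod("applyRigid", signature("RigidTransform", "LandmarkSet"),
  function(transform, x, ...) {
    if (ncol(x@coords) != 3L) stop("rigid transforms act on 3D landmarks")
    co <- sweep(x@coords %*% t(transform@rotation), 2L,
                transform@translation, "+")
    rownames(co) <- rownames(x@coords)
    new("LandmarkSet", spaceName = x@spaceName, coords = co)
  })

#' @rdname applyRigid
#' @export
setMethod("applyRigid", signature("RigidTransform", "Volume"),
  function(transform, x, reference = NULL,
           interpolation = c("linear", "nearest"), ...) {
    interpolation <- match.arg(interpolation)
    if (is.null(reference)) reference <- x
    inv <- invertRigid(transform)
    worldMap <- function(p)
      sweep(p %*% t(inv@rotation), 2L, inv@translation, "+")
    .resampleVolume(x, reference, worldMap, interpolation,
                    spaceName = reference@spaceName)
  })

#' Compose and invert rigid transforms
#'
#' \code{composeRigid(a, b)} returns the transform acting as
#' \code{a(b(p))} for every point p — used, e.g., to stack an in vivo
#' angulation correction on top of the specimen alignment.
#'
#' @param a,b,transform \linkS4class{RigidTransform}s.
#' @return A \linkS4class{RigidTransform}.
#' @export
composeRigid <- function(a, b) {
  RigidTransform(rotation = a@rotation %*% b@rotation,
                 translation = drop(a@rotation %*% b@translation) +
                   a@translation)
}

#' @rdname composeRigid
#' @export
invertRigid <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(rotation = Rt,
                 translation = -drop(Rt %*% transform@translation))
}

#' Rotation angle between two rotation matrices
#'
#' Geodesic distance on SO(3): the angle of the relative rotation
#' \eqn{R_1 R_2^T}, in radians.
#'
#' @param r1,r2 3x3 rotation matrices.
#' @return Angle in radians, in [0, pi].
#' @export
rotationAngleDistance <- function(r1, r2 = diag(3)) {
  ## |R1 - R2|_F = 2*sqrt(2)*|sin(theta/2)|; stable down to machine epsilon,
  ## unlike the trace/acos form
  fro <- sqrt(sum((r1 - r2)^2))
  2 * asin(pmin(1, fro / (2 * sqrt(2))))
}
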