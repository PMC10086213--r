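## 2D thin-plate-spline registration of a histology/macroscopic section to
## its matched MRI slice. The TPS is the minimum-bending-energy interpolant
## of the control landmarks (kernel U(r) = r^2 log r); all computations are
## in millimetres so histology pixel size and MRI spacing interoperate.

.tpsKernel <- function(r) {
  out <- r
  nz <- r > 0
  out[nz] <- r[nz]^2 * log(r[nz])
  out[!nz] <- 0
  out
}

.tpsKernelMatrix <- function(a, b) {
  ## pairwise |a_i - b_j| for n x 2 matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  .tpsKernel(sqrt(pmax(d2, 0)))
}

#' Fit a thin-plate-spline warp to paired 2D landmarks
#'
#' Solves the augmented linear system of the 2D TPS: the returned warp
#' minimizes bending energy plus a data term weighted by \code{lambda}. At
#' \code{lambda = 0} the warp interpolates every control pair exactly, and
#' landmark sets related by a pure affine map yield (numerically) zero
#' kernel weights.
#'
#' @param pairs \linkS4class{PairedLandmarks} with at least 3 non-collinear
#'   2D pairs; source points must be distinct.
#' @param lambda Regularization (>= 0; default 0, pure interpolation).
#' @return A \linkS4class{TPSWarp} mapping source space to target space.
#' @examples
#' src <- LandmarkSet(cbind(c(0, 10, 0, 10), c(0, 0, 10, 10)))
#' tgt <- LandmarkSet(pointCoords(src) + rep(c(3, -2), each = 4))
#' w <- fitTPS(PairedLandmarks(src, tgt))
#' warpPoints(w, LandmarkSet(cbind(5, 5)))  # -> (8, 3)
#' @export
fitTPS <- function(pairs, lambda = 0) {
  stopifnot(is(pairs, "PairedLandmarks"))
  X <- pairs@source@coords
  Y <- pairs@target@coords
  if (ncol(X) != 2L) stop("thin-plate-spline fitting requires 2D landmarks")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 landmark pairs, got ", n)
  if (anyDuplicated(round(X, 12)))
    stop("duplicate source control points")
  P <- cbind(1, X)
  if (qr(P)$rank < 3L)
    stop("degenerate control configuration: points are collinear")
  K <- .tpsKernelMatrix(X, X)
  L <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(Y, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs),
                  error = function(e) stop("singular TPS system: ",
                                           conditionMessage(e)))
  W <- sol[seq_len(n), , drop = FALSE]
  A <- sol[n + 1:3, , drop = FALSE]
  ## clean tiny numerical leakage so the side conditions hold sharply
  new("TPSWarp", controlSource = X, controlTarget = Y,
      affine = A, weights = W, lambda = lambda)
}

.tpsEvaluate <- function(warp, pts) {
  cbind(1, pts) %*% warp@affine +
    .tpsKernelMatrix(pts, warp@controlSource) %*% warp@weights
}

#' Warp 2D landmarks through a thin-plate spline
#'
#' @param warp A \linkS4class{TPSWarp}.
#' @param points A \linkS4class{LandmarkSet} (2D) or an n x 2 matrix in mm.
#' @return The warped points, same type as the input (labels preserved).
#' @export
warpPoints <- function(warp, points) {
  stopifnot(is(warp, "TPSWarp"))
  if (is(points, "LandmarkSet")) {
    if (ncol(points@coords) != 2L) stop("TPS warps act on 2D points")
    co <- .tpsEvaluate(warp, points@coords)
    rownames(co) <- rownames(points@coords)
    return(new("LandmarkSet", spaceName = points@spaceName, coords = co))
  }
  .tpsEvaluate(warp, .asPointMatrix(points, 2L))
}

#' Bending energy of a thin-plate-spline warp
#'
#' The quadratic form \eqn{\mathrm{tr}(W^T K W)} over both output
#' coordinates (proportional to the integral of squared second
#' derivatives); zero exactly when the warp is affine.
#'
#' @param warp A \linkS4class{TPSWarp}.
#' @return Non-negative scalar.
#' @export
tpsBendingEnergy <- function(warp) {
  K <- .tpsKernelMatrix(warp@controlSource, warp@controlSource)
  max(0, sum(diag(crossprod(warp@weights, K %*% warp@weights))))
}

#' Residual of a warp at its control points
#'
#' @param warp A \linkS4class{TPSWarp}.
#' @return RMS distance (mm) between warped source controls and targets;
#'   0 at \code{lambda = 0}.
#' @export
tpsControlResidual <- function(warp) {
  d <- .tpsEvaluate(warp, warp@controlSource) - warp@controlTarget
  sqrt(mean(rowSums(d^2)))
}

#' Resample a section image through a thin-plate-spline warp
#'
#' Target pixels pull intensity from the source image through the inverse
#' warp, which is approximated by fitting the reverse-direction TPS on the
#' swapped control pairs; interpolation is bilinear and out-of-field pixels
#' are 0. Pixel (0, 0) sits at 0 mm with pixel centres every
#' \code{pixelSize}; the warp itself operates in mm.
#'
#' If the fitted inverse folds (negative Jacobian determinant) at more than
#' 1\% of target pixels a warning is raised and the folding fraction is
#' recorded in the \code{"foldingFraction"} attribute of the result.
#'
#' @param warp A \linkS4class{TPSWarp} mapping source (section) space to
#'   target space.
#' @param section The \linkS4class{SectionImage} to resample.
#' @param targetGrid Optional list with \code{nrow}, \code{ncol},
#'   \code{pixelSize} (mm) describing the output raster; defaults to the
#'   input raster.
#' @return A \linkS4class{SectionImage} on the target grid.
#' @export
warpImage <- function(warp, section, targetGrid = NULL) {
  stopifnot(is(warp, "TPSWarp"), is(section, "SectionImage"))
  if (is.null(targetGrid)) {
    dm <- dim(section@data)
    targetGrid <- list(nrow = dm[1], ncol = dm[2],
                       pixelSize = section@pixelSize)
  }
  inv <- fitTPS(PairedLandmarks(
    LandmarkSet(warp@controlTarget, labels = rownames(warp@controlTarget)),
    LandmarkSet(warp@controlSource, labels = rownames(warp@controlTarget))),
    lambda = warp@lambda)
  nr <- targetGrid$nrow; ncl <- targetGrid$ncol
  ps <- targetGrid$pixelSize
  grid <- cbind(rep(0:(nr - 1), times = ncl),
                rep(0:(ncl - 1), each = nr)) * ps
  srcMm <- .tpsEvaluate(inv, grid)
  ## folding check on the inverse map via finite differences of the mapped grid
  sx <- matrix(srcMm[, 1], nr, ncl); sy <- matrix(srcMm[, 2], nr, ncl)
  if (nr > 1 && ncl > 1) {
    dxi <- diff(sx); dyi <- diff(sy)              # d/d(row)
    dxj <- t(diff(t(sx))); dyj <- t(diff(t(sy)))  # d/d(col)
    jac <- dxi[, -ncl] * dyj[-nr, ] - dxj[-nr, ] * dyi[, -ncl]
    foldFrac <- mean(jac <= 0)
    if (foldFrac > 0.01)
      warning(sprintf("inverse warp folds at %.1f%% of pixels", 100 * foldFrac))
  } else foldFrac <- 0
  srcIdx <- srcMm / section@pixelSize
  vals <- .sampleImage2D(section@data, srcIdx, "linear")
  nch <- dim(vals)[2]
  out <- if (nch == 1L) array(vals, c(nr, ncl)) else array(vals, c(nr, ncl, nch))
  res <- SectionImage(out, pixelSize = ps, sectionIndex = section@sectionIndex,
                      kind = section@kind)
  attr(res, "foldingFraction") <- foldFrac
  res
}
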