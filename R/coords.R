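## World <-> index coordinate conversions and grid resampling. Indices are
## zero-based and continuous, matching NIfTI conventions; voxel centres carry
## the coordinates.

#' Convert between voxel indices and world coordinates
#'
#' World coordinates are RAS millimetres: the world position of zero-based
#' (continuous) index i is \code{origin + direction \%*\% (spacing * i)}.
#'
#' @param volume A \linkS4class{Volume}.
#' @param index n x 3 matrix (or length-3 vector) of zero-based voxel indices.
#' @param world n x 3 matrix (or length-3 vector) of world coordinates in mm.
#' @return n x 3 matrix of world coordinates (\code{indexToWorld}) or
#'   zero-based continuous indices (\code{worldToIndex}).
#' @examples
#' v <- Volume(array(0, c(5, 5, 5)), spacing = c(2, 2, 2))
#' indexToWorld(v, c(1, 1, 1))   # (2, 2, 2) mm
#' @export
indexToWorld <- function(volume, index) {
  index <- .asPointMatrix(index, 3L)
  sweep(t(volume@direction %*% (t(index) * volume@spacing)), 2L,
        volume@origin, "+")
}

#' @rdname indexToWorld
#' @export
worldToIndex <- function(volume, world) {
  world <- .asPointMatrix(world, 3L)
  t((t(volume@direction) %*% t(sweep(world, 2L, volume@origin, "-"))) /
      volume@spacing)
}

.asPointMatrix <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, ncol = d, byrow = TRUE)
  storage.mode(x) <- "double"
  x
}

## snap indices a hair outside the grid (floating-point noise from coordinate
## round trips) back onto the boundary; genuinely out-of-field stays out
.clampBoundary <- function(idx, dm, tol = 1e-6) {
  for (k in seq_len(ncol(idx))) {
    lo <- idx[, k] > -tol & idx[, k] < 0
    hi <- idx[, k] > dm[k] - 1 & idx[, k] < dm[k] - 1 + tol
    idx[lo, k] <- 0
    idx[hi, k] <- dm[k] - 1
  }
  idx
}

## Sample a 3D array at continuous zero-based indices; out-of-grid -> 0.
## 'idx' is n x 3. Vectorized trilinear / nearest-neighbour gather.
.sampleArray3D <- function(arr, idx, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dm <- dim(arr)
  idx <- .clampBoundary(idx, dm)
  n <- nrow(idx)
  out <- numeric(n)
  if (interpolation == "nearest") {
    ii <- round(idx)
    ok <- ii[, 1] >= 0 & ii[, 1] <= dm[1] - 1 &
          ii[, 2] >= 0 & ii[, 2] <= dm[2] - 1 &
          ii[, 3] >= 0 & ii[, 3] <= dm[3] - 1
    lin <- ii[ok, 1] + dm[1] * (ii[ok, 2] + dm[2] * ii[ok, 3]) + 1
    out[ok] <- arr[lin]
    return(out)
  }
  f <- floor(idx)
  w <- idx - f
  ok <- f[, 1] >= 0 & f[, 1] <= dm[1] - 2 &
        f[, 2] >= 0 & f[, 2] <= dm[2] - 2 &
        f[, 3] >= 0 & f[, 3] <= dm[3] - 2
  ## points exactly on the far face still have full support
  edge <- function(k) idx[, k] == dm[k] - 1
  onFace <- (f[, 1] >= 0 & f[, 2] >= 0 & f[, 3] >= 0) &
    (edge(1) | edge(2) | edge(3)) &
    idx[, 1] <= dm[1] - 1 & idx[, 2] <= dm[2] - 1 & idx[, 3] <= dm[3] - 1
  if (any(onFace)) {
    f[onFace, ] <- pmin(f[onFace, , drop = FALSE],
                        matrix(dm - 2, sum(onFace), 3, byrow = TRUE))
    w[onFace, ] <- idx[onFace, , drop = FALSE] - f[onFace, , drop = FALSE]
    ok <- ok | (onFace & f[, 1] >= 0 & f[, 2] >= 0 & f[, 3] >= 0)
  }
  if (!any(ok)) return(out)
  fo <- f[ok, , drop = FALSE]
  wo <- w[ok, , drop = FALSE]
  base <- fo[, 1] + dm[1] * (fo[, 2] + dm[2] * fo[, 3]) + 1
  acc <- numeric(sum(ok))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (if (dx) wo[, 1] else 1 - wo[, 1]) *
          (if (dy) wo[, 2] else 1 - wo[, 2]) *
          (if (dz) wo[, 3] else 1 - wo[, 3])
    acc <- acc + wt * arr[base + dx + dm[1] * (dy + dm[2] * dz)]
  }
  out[ok] <- acc
  out
}

## Resample 'volume' onto the grid of 'reference' through world map
## worldMap: target world point -> source world point (a function taking and
## returning an n x 3 matrix).
.resampleVolume <- function(volume, reference, worldMap,
                            interpolation = c("linear", "nearest"),
                            spaceName = reference@spaceName) {
  interpolation <- match.arg(interpolation)
  dm <- dim(reference@data)
  grid <- as.matrix(expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1),
                                k = 0:(dm[3] - 1)))
  tw <- indexToWorld(reference, grid)
  sw <- worldMap(tw)
  si <- worldToIndex(volume, sw)
  vals <- .sampleArray3D(volume@data, si, interpolation)
  Volume(array(vals, dm), spacing = reference@spacing,
         origin = reference@origin, direction = reference@direction,
         spaceName = spaceName)
}

## Bilinear / nearest sampling of a 2D (or h x w x c) image at continuous
## zero-based (row, col) indices; out-of-grid -> 0.
.sampleImage2D <- function(img, idx, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dm <- dim(img)
  idx <- .clampBoundary(idx, dm[seq_len(ncol(idx))])
  nc <- if (length(dm) == 3L) dm[3] else 1L
  n <- nrow(idx)
  out <- matrix(0, n, nc)
  if (interpolation == "nearest") {
    ii <- round(idx)
    ok <- ii[, 1] >= 0 & ii[, 1] <= dm[1] - 1 & ii[, 2] >= 0 & ii[, 2] <= dm[2] - 1
    lin <- ii[ok, 1] + dm[1] * ii[ok, 2] + 1
    for (c in seq_len(nc))
      out[ok, c] <- img[lin + (c - 1) * dm[1] * dm[2]]
    return(out)
  }
  f <- floor(idx)
  onFace <- (f[, 1] >= 0 & f[, 2] >= 0) &
    (idx[, 1] == dm[1] - 1 | idx[, 2] == dm[2] - 1) &
    idx[, 1] <= dm[1] - 1 & idx[, 2] <= dm[2] - 1
  if (any(onFace))
    f[onFace, ] <- pmin(f[onFace, , drop = FALSE],
                        matrix(dm[1:2] - 2, sum(onFace), 2, byrow = TRUE))
  w <- idx - f
  ok <- f[, 1] >= 0 & f[, 1] <= dm[1] - 2 & f[, 2] >= 0 & f[, 2] <= dm[2] - 2 &
        w[, 1] >= 0 & w[, 1] <= 1 & w[, 2] >= 0 & w[, 2] <= 1
  if (!any(ok)) return(out)
  fo <- f[ok, , drop = FALSE]
  wo <- w[ok, , drop = FALSE]
  base <- fo[, 1] + dm[1] * fo[, 2] + 1
  np <- dm[1] * dm[2]
  for (c in seq_len(nc)) {
    off <- (c - 1) * np
    acc <- (1 - wo[, 1]) * (1 - wo[, 2]) * img[base + off] +
           wo[, 1] * (1 - wo[, 2]) * img[base + 1 + off] +
           (1 - wo[, 1]) * wo[, 2] * img[base + dm[1] + off] +
           wo[, 1] * wo[, 2] * img[base + dm[1] + 1 + off]
    out[ok, c] <- acc
  }
  out
}

#' Extract one slice of a volume as a 2D image with in-plane geometry
#'
#' The slice plane inherits the two in-plane axes of the volume; pixel (0,0)
#' sits at the world position of the first in-plane voxel of that slice.
#'
#' @param volume A \linkS4class{Volume}.
#' @param slice 1-based slice index along \code{axis}.
#' @param axis Index axis orthogonal to the slice plane (default 3).
#' @return A list with \code{data} (2D matrix), \code{pixelSize} (mm; mean of
#'   the two in-plane spacings), and \code{worldOrigin} (3-vector, mm).
#' @export
extractSlice <- function(volume, slice, axis = 3L) {
  dm <- dim(volume@data)
  if (slice < 1L || slice > dm[axis]) stop("slice index out of range")
  inPlane <- setdiff(1:3, axis)
  idx0 <- c(0, 0, 0); idx0[axis] <- slice - 1
  sl <- switch(axis,
               volume@data[slice, , ], volume@data[, slice, ],
               volume@data[, , slice])
  list(data = sl, pixelSize = mean(volume@spacing[inPlane]),
       worldOrigin = drop(indexToWorld(volume, idx0)))
}
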