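## Synthetic specimen phantom with known ground truth for every pipeline
## stage: an in vivo tumor volume, a rigidly re-oriented ex vivo copy,
## smoothly deformed 2D "histology" sections with noisy paired landmarks,
## and 4-habitat parametric map stacks. Every generator is a pure function
## of its seed.

#' Reference per-habitat parametric map statistics
#'
#' Mean and SD of each of the eight quantitative channels for the four
#' reference tumor habitats A-D (cell-rich, sclerotic, myxoid, predominantly
#' myxoid), used as the default generator parameters of
#' \code{\link{makeMapStack}}. The fourth DCE channel (\code{vp} slot)
#' carries the initial-area-under-the-curve (iAUC) values in arbitrary
#' units.
#'
#' @return A list with \code{mean} and \code{sd} (4 x 8 matrices, rows A-D,
#'   columns \code{\link{channelNames}}) and \code{units}.
#' @export
habitatReferenceParams <- function() {
  ch <- channelNames()
  mean <- matrix(c(
    ## ADC,  Dstar,   f, fDstar, Ktrans,  kep,    ve,   vp(iAUC)
    1776.2,  34.7, 4.4,   1.2,  313.2,  44.2, 759.8, 17.6,
    1181.7,  39.4, 8.6,   2.8,  347.3,  88.3, 388.6, 16.7,
    1647.3,  31.6, 10.1,  2.3,  112.2,  22.3, 710.8,  6.5,
    2212.3,  35.4, 4.8,   1.3,   64.2,  18.6, 705.9,  4.8),
    nrow = 4, byrow = TRUE, dimnames = list(LETTERS[1:4], ch))
  sd <- matrix(c(
    184.0, 1.9, 2.1, 0.6, 130.9, 15.1, 360.1, 6.7,
     93.4, 6.5, 5.5, 1.4, 110.4, 22.6,  61.5, 4.3,
    203.6, 4.3, 5.0, 1.0,  42.8, 12.3, 397.0, 2.3,
    188.3, 2.4, 1.0, 0.3,  61.4, 10.7, 724.7, 4.1),
    nrow = 4, byrow = TRUE, dimnames = list(LETTERS[1:4], ch))
  units <- .defaultUnits()
  units["vp"] <- "a.u. (iAUC)"
  list(mean = mean, sd = sd, units = units)
}

#' Random proper rigid transform
#'
#' Rotation about a uniformly random axis by a uniform angle in
#' \code{[0, maxAngleDeg]}, plus a uniform translation in
#' \code{[-maxShiftMm, maxShiftMm]} per axis.
#'
#' @param seed Integer RNG seed.
#' @param maxAngleDeg Maximum rotation angle in degrees.
#' @param maxShiftMm Maximum per-axis translation in mm.
#' @return A \linkS4class{RigidTransform}.
#' @export
randomRigidTransform <- function(seed = 1L, maxAngleDeg = 30,
                                 maxShiftMm = 8) {
  withr::with_seed(seed, {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, maxAngleDeg) * pi / 180
    tr <- stats::runif(3, -maxShiftMm, maxShiftMm)
    RigidTransform(rotation = rotationAboutAxis(ax, ang), translation = tr)
  })
}

## smooth a 3D array with a separable Gaussian (circular edges)
.smooth3d <- function(arr, sigmaVox = 2) {
  klen <- max(3L, 2L * ceiling(2.5 * sigmaVox) + 1L)
  k <- stats::dnorm(seq(-(klen %/% 2), klen %/% 2), sd = sigmaVox)
  k <- k / sum(k)
  dm <- dim(arr)
  pass <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = dm[axis])
    f <- stats::filter(m, k, circular = TRUE)
    aperm(array(as.numeric(f), dm[perm]), order(perm))
  }
  pass(pass(pass(arr, 1L), 2L), 3L)
}

#' Synthesize an in vivo tumor phantom
#'
#' A smooth ellipsoidal tumor with low-order lobulated margins and internal
#' texture on a regular grid, plus a binary tumor ROI and 3D landmarks
#' placed on intensity contours inside and on the tumor. Deterministic under
#' the seed.
#'
#' @param gridDim Grid size in voxels (length 3).
#' @param spacingMm Voxel spacing in mm (length 3).
#' @param radiiMm Ellipsoid semi-axes in mm (length 3).
#' @param lobulation Relative amplitude of the margin lobulation (0-0.3).
#' @param nLandmarks Number of landmarks (30-40 in the reference protocol).
#' @param seed Integer RNG seed.
#' @return A list with \code{volume} (\linkS4class{Volume}, space
#'   \code{"in_vivo"}), \code{roi} (binary label \linkS4class{Volume}),
#'   \code{landmarks} (3D \linkS4class{LandmarkSet}), and \code{truth}
#'   (list: \code{center}, \code{radiiMm}, \code{requestedVolumeMl} — the
#'   analytic ellipsoid volume).
#' @export
makeInvivoPhantom <- function(gridDim = c(56, 56, 40),
                              spacingMm = c(1.5, 1.5, 2),
                              radiiMm = c(22, 18, 16), lobulation = 0.1,
                              nLandmarks = 35L, seed = 1L) {
  stopifnot(length(gridDim) == 3L, length(radiiMm) == 3L)
  if (lobulation < 0 || lobulation > 0.3)
    stop("lobulation must lie in [0, 0.3]")
  extent <- gridDim * spacingMm
  center <- extent / 2
  if (any(radiiMm * (1 + lobulation) >= extent / 2 - spacingMm))
    stop("tumor larger than grid")
  withr::with_seed(seed, {
    lobPhase <- stats::runif(3, 0, 2 * pi)
    lobW <- stats::rnorm(3, 0, 1)
    lobW <- lobW / max(1, max(abs(lobW)))
    grid <- as.matrix(expand.grid(i = 0:(gridDim[1] - 1),
                                  j = 0:(gridDim[2] - 1),
                                  k = 0:(gridDim[3] - 1)))
    w <- sweep(grid, 2L, spacingMm, "*")
    u <- sweep(sweep(w, 2L, center, "-"), 2L, radiiMm, "/")
    r <- sqrt(rowSums(u^2))
    theta <- atan2(u[, 2], u[, 1])
    zc <- ifelse(r > 0, u[, 3] / r, 0)
    ## the z-dependent term has spherical mean cos(phase)/3; subtract it so
    ## the lobulation is mean-zero and the analytic ellipsoid volume holds
    lobC <- lobW[3] * cos(lobPhase[3]) / 3
    lobe <- lobW[1] * cos(2 * theta + lobPhase[1]) * (1 - zc^2) +
            lobW[2] * sin(3 * theta + lobPhase[2]) * (1 - zc^2) +
            lobW[3] * cos(2 * asin(pmin(1, pmax(-1, zc))) + lobPhase[3]) - lobC
    boundary <- 1 + lobulation * lobe
    roiMaskArr <- array(as.numeric(r <= boundary), gridDim)
    texture <- .smooth3d(array(stats::rnorm(prod(gridDim)), gridDim),
                         sigmaVox = 2)
    texture <- texture / max(abs(texture))
    vol <- array(0.15, gridDim) + 0.02 * texture
    inside <- roiMaskArr > 0
    vol[inside] <- 0.55 + 0.35 * texture[inside]
    ## landmarks on contours of marked tumor portions: points on scaled
    ## copies of the lobulated margin, strictly inside the field of view
    az <- stats::runif(nLandmarks, 0, 2 * pi)
    el <- acos(stats::runif(nLandmarks, -1, 1))
    scl <- stats::runif(nLandmarks, 0.55, 0.98)
    dirs <- cbind(sin(el) * cos(az), sin(el) * sin(az), cos(el))
    zl <- dirs[, 3]
    lobeL <- lobW[1] * cos(2 * atan2(dirs[, 2], dirs[, 1]) + lobPhase[1]) * (1 - zl^2) +
             lobW[2] * sin(3 * atan2(dirs[, 2], dirs[, 1]) + lobPhase[2]) * (1 - zl^2) +
             lobW[3] * cos(2 * asin(pmin(1, pmax(-1, zl))) + lobPhase[3]) - lobC
    radL <- (1 + lobulation * lobeL) * scl
    pts <- sweep(dirs * radL, 2L, radiiMm, "*")
    pts <- sweep(pts, 2L, center, "+")
  })
  volume <- Volume(vol, spacing = spacingMm, spaceName = "in_vivo")
  roi <- Volume(roiMaskArr, spacing = spacingMm, spaceName = "in_vivo")
  list(volume = volume, roi = roi,
       landmarks = LandmarkSet(pts, spaceName = "in_vivo"),
       truth = list(center = center, radiiMm = radiiMm,
                    requestedVolumeMl = 4 / 3 * pi * prod(radiiMm) / 1000,
                    seed = seed))
}

#' Synthesize the ex vivo copy of an in vivo phantom
#'
#' Applies a rigid re-orientation (random by default, standing in for the
#' arbitrary pose of the specimen in the agarose block) and an optional
#' isotropic shrinkage about the tumor centroid, to both the volume and the
#' landmarks; the exact transform is recorded as ground truth.
#'
#' @param invivo Result of \code{\link{makeInvivoPhantom}} (or a list with
#'   \code{volume}, \code{roi}, \code{landmarks}, \code{truth$center}).
#' @param rigid Optional \linkS4class{RigidTransform}; random under
#'   \code{seed} if NULL.
#' @param shrink Isotropic shrink factor in [0.8, 1], modelling slight
#'   concentric fixation shrinkage (default 1 = none).
#' @param seed Integer RNG seed (used only when \code{rigid} is NULL).
#' @return A list with \code{volume}, \code{roi}, \code{landmarks} (all in
#'   space \code{"ex_vivo_1"}), and \code{truth} (list: \code{rigid} — the
#'   in-vivo-to-ex-vivo \linkS4class{RigidTransform}, \code{shrink},
#'   \code{center}).
#' @export
makeExvivoPhantom <- function(invivo, rigid = NULL, shrink = 1.0, seed = 1L) {
  if (shrink < 0.8 || shrink > 1.0)
    stop("shrink factor must lie in [0.8, 1.0]")
  if (is.null(rigid)) rigid <- randomRigidTransform(seed)
  ctr <- invivo$truth$center
  R <- rigid@rotation
  ## full forward map: p -> R (s (p - c)) + c + t
  fwd <- function(p)
    sweep(sweep(p, 2L, ctr, "-") %*% t(R) * shrink, 2L,
          ctr + rigid@translation, "+")
  bwd <- function(p)
    sweep(sweep(p, 2L, ctr + rigid@translation, "-") %*% R / shrink, 2L,
          ctr, "+")
  vol <- .resampleVolume(invivo$volume, invivo$volume, bwd, "linear",
                         spaceName = "ex_vivo_1")
  roi <- .resampleVolume(invivo$roi, invivo$roi, bwd, "nearest",
                         spaceName = "ex_vivo_1")
  lm <- LandmarkSet(fwd(invivo$landmarks@coords),
                    labels = rownames(invivo$landmarks@coords),
                    spaceName = "ex_vivo_1")
  ## rigid-equivalent truth (exact when shrink == 1)
  truthRigid <- RigidTransform(
    rotation = R,
    translation = ctr + rigid@translation - drop(R %*% ctr) * shrink)
  list(volume = vol, roi = roi, landmarks = lm,
       truth = list(rigid = truthRigid, shrink = shrink, center = ctr))
}

#' Synthesize a deformed 2D histology section with paired landmarks
#'
#' Applies a smooth ground-truth deformation to an MRI slice — modelling the
#' light deformations, split and microtomy artifacts of real sections — and
#' generates paired landmarks: the MRI-side point is the original position,
#' the histology-side point the deformed position plus annotation noise.
#'
#' Two deformation families are available: \code{"affine"} (rotation,
#' anisotropic scale, shear and shift, scaled so the largest in-field
#' displacement equals \code{amplitudeMm}) lies in the span recoverable from
#' any landmark subset, so split-based protocols recover it exactly;
#' \code{"tps"} (independent Gaussian control displacements with SD
#' \code{amplitudeMm} on a coarse grid) is a generic smooth deformation that
#' split-based protocols can only recover approximately.
#'
#' @param sliceData 2D matrix (an MRI slice, e.g. from
#'   \code{\link{extractSlice}}).
#' @param pixelSizeMm In-plane pixel size in mm.
#' @param amplitudeMm Deformation amplitude in mm (>= 0).
#' @param deformation \code{"affine"} or \code{"tps"}.
#' @param nControlGrid Control grid per side for the \code{"tps"} family.
#' @param nLandmarks Number of paired landmarks (30-40 typical).
#' @param noiseSigmaMm Isotropic per-axis Gaussian landmark noise in mm.
#' @param noiseOn Which side receives noise: \code{"source"} (histology,
#'   default), \code{"both"}, or \code{"none"}.
#' @param sectionIndex Zero-based section index recorded in the image.
#' @param seed Integer RNG seed.
#' @return A list with \code{section} (\linkS4class{SectionImage}),
#'   \code{pairs} (\linkS4class{PairedLandmarks}: histology source, MRI
#'   target), \code{truthWarp} (\linkS4class{TPSWarp}, MRI to histology),
#'   and \code{noiseSigmaMm}.
#' @export
makeSectionPhantom <- function(sliceData, pixelSizeMm, amplitudeMm = 3,
                               deformation = c("affine", "tps"),
                               nControlGrid = 4L, nLandmarks = 35L,
                               noiseSigmaMm = 0,
                               noiseOn = c("source", "both", "none"),
                               sectionIndex = 0L, seed = 1L) {
  deformation <- match.arg(deformation)
  noiseOn <- match.arg(noiseOn)
  if (amplitudeMm < 0) stop("deformation amplitude must be >= 0")
  dm <- dim(sliceData)
  extent <- (dm - 1) * pixelSizeMm
  ctr <- extent / 2
  gx <- seq(0, extent[1], length.out = nControlGrid)
  gy <- seq(0, extent[2], length.out = nControlGrid)
  ctrl <- as.matrix(expand.grid(x = gx, y = gy))
  withr::with_seed(seed, {
    if (deformation == "affine") {
      E <- matrix(stats::rnorm(4, 0, 0.05), 2, 2)
      tr <- stats::rnorm(2, 0, 1)
      disp <- function(p)
        sweep(sweep(p, 2L, ctr, "-") %*% t(E), 2L, tr, "+")
      mx <- max(sqrt(rowSums(disp(ctrl)^2)))
      s <- if (mx > 0 && amplitudeMm > 0) amplitudeMm / mx else 0
      tgtCtrl <- ctrl + s * disp(ctrl)
    } else {
      tgtCtrl <- ctrl + matrix(stats::rnorm(length(ctrl), 0, amplitudeMm),
                               ncol = 2)
    }
    truthWarp <- fitTPS(PairedLandmarks(LandmarkSet(ctrl),
                                        LandmarkSet(tgtCtrl)))
    ## landmarks in the central 80% of the field
    mriPts <- cbind(stats::runif(nLandmarks, 0.1, 0.9) * extent[1],
                    stats::runif(nLandmarks, 0.1, 0.9) * extent[2])
    histPts <- .tpsEvaluate(truthWarp, mriPts)
    if (noiseSigmaMm > 0 && noiseOn != "none") {
      histPts <- histPts + matrix(stats::rnorm(2 * nLandmarks, 0,
                                               noiseSigmaMm), ncol = 2)
      if (noiseOn == "both")
        mriPts <- mriPts + matrix(stats::rnorm(2 * nLandmarks, 0,
                                               noiseSigmaMm), ncol = 2)
    }
  })
  labels <- sprintf("L%02d", seq_len(nLandmarks))
  mriImage <- SectionImage(sliceData, pixelSize = pixelSizeMm,
                           sectionIndex = sectionIndex,
                           kind = "macroscopic")
  section <- suppressWarnings(warpImage(truthWarp, mriImage))
  section@kind <- "histology_HE"
  pairs <- PairedLandmarks(
    LandmarkSet(histPts, labels = labels, spaceName = "histology"),
    LandmarkSet(mriPts, labels = labels, spaceName = "ex_vivo_2"))
  list(section = section, pairs = pairs, truthWarp = truthWarp,
       noiseSigmaMm = noiseSigmaMm)
}

#' Synthesize a 4-habitat parametric map stack
#'
#' Partitions the ROI into contiguous habitat blobs (Voronoi cells of
#' randomly seeded ROI voxels) and draws each voxel's eight channel values
#' independently from the per-habitat normal distributions; negative draws
#' are clipped at 0 and counted.
#'
#' @param roi Binary/label \linkS4class{Volume} defining the tumor ROI.
#' @param nHabitats Number of habitats (2-8; default 4).
#' @param params List with \code{mean} and \code{sd} matrices
#'   (nHabitats x 8, columns \code{\link{channelNames}}) and optional
#'   \code{units}; defaults to \code{\link{habitatReferenceParams}}.
#' @param seed Integer RNG seed.
#' @return A list with \code{stack} (\linkS4class{ParametricMapStack}),
#'   \code{habitatLabels} (ground-truth label \linkS4class{Volume}),
#'   \code{params}, and \code{nClipped}.
#' @export
makeMapStack <- function(roi, nHabitats = 4L, params = habitatReferenceParams(),
                         seed = 1L) {
  stopifnot(is(roi, "Volume"))
  if (nHabitats < 2L || nHabitats > 8L) stop("nHabitats must lie in 2..8")
  if (any(params$sd < 0)) stop("habitat SDs must be >= 0")
  if (nrow(params$mean) < nHabitats)
    stop("params must provide one row per habitat")
  roiIdx <- which(roi@data > 0)
  if (length(roiIdx) < nHabitats) stop("ROI too small for habitat layout")
  dm <- dim(roi@data)
  coords <- cbind((roiIdx - 1) %% dm[1],
                  ((roiIdx - 1) %/% dm[1]) %% dm[2],
                  (roiIdx - 1) %/% (dm[1] * dm[2]))
  coords <- sweep(coords, 2L, roi@spacing, "*")
  nClipped <- 0L
  withr::with_seed(seed, {
    ## centroidal Voronoi blobs: contiguous and reasonably size-balanced
    seeds <- coords[sample.int(nrow(coords), nHabitats), , drop = FALSE]
    habitat <- suppressWarnings(
      stats::kmeans(coords, centers = seeds, iter.max = 200L,
                    algorithm = "Lloyd"))$cluster
    labArr <- array(0, dm)
    labArr[roiIdx] <- habitat
    channels <- list()
    for (nm in channelNames()) {
      vals <- stats::rnorm(length(roiIdx),
                           mean = params$mean[habitat, nm],
                           sd = params$sd[habitat, nm])
      nClipped <- nClipped + sum(vals < 0)
      vals[vals < 0] <- 0
      arr <- array(0, dm)
      arr[roiIdx] <- vals
      channels[[nm]] <- Volume(arr, spacing = roi@spacing,
                               origin = roi@origin,
                               direction = roi@direction,
                               spaceName = roi@spaceName)
    }
  })
  units <- if (!is.null(params$units)) params$units else .defaultUnits()
  stack <- ParametricMapStack(channels, roi = roi, units = units)
  list(stack = stack,
       habitatLabels = Volume(labArr, spacing = roi@spacing,
                              origin = roi@origin, direction = roi@direction,
                              spaceName = roi@spaceName),
       params = params, nClipped = nClipped)
}
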