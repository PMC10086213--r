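test_that("in vivo phantom honors its volume request and is reproducible", {
  inv <- makeInvivoPhantom(seed = 1)
  voxMl <- sum(volData(inv$roi) > 0) * prod(spacing(inv$roi)) / 1000
  expect_lt(abs(voxMl / inv$truth$requestedVolumeMl - 1), 0.1)

  inv2 <- makeInvivoPhantom(seed = 1)
  expect_identical(volData(inv2$volume), volData(inv$volume))
  expect_identical(pointCoords(inv2$landmarks), pointCoords(inv$landmarks))

  # landmark count configurable in the 30-40 range, all inside the field
  inv3 <- makeInvivoPhantom(nLandmarks = 40L, seed = 2)
  expect_equal(length(inv3$landmarks), 40L)
  ext <- dim(volData(inv3$volume)) * spacing(inv3$volume)
  co <- pointCoords(inv3$landmarks)
  expect_true(all(co > 0 & co < rep(ext, each = 40)))

  expect_error(makeInvivoPhantom(radiiMm = c(60, 60, 60), seed = 1),
               "larger than grid")
})

test_that("ex vivo phantom records a recoverable rigid truth", {
  inv <- makeInvivoPhantom(seed = 3)
  # identity + no shrink: untouched volume (resampling on the same grid)
  ex0 <- makeExvivoPhantom(inv, rigid = RigidTransform(), shrink = 1)
  expect_equal(volData(ex0$volume), volData(inv$volume), tolerance = 1e-9)
  expect_equal(pointCoords(ex0$landmarks), pointCoords(inv$landmarks),
               tolerance = 1e-12)

  # known oblique 25-degree rotation: rigid estimation on the noiseless
  # landmark pairs recovers it end to end
  tf <- RigidTransform(rotationAboutAxis(c(1, 2, -1) / sqrt(6),
                                         25 * pi / 180), c(4, -6, 3))
  ex <- makeExvivoPhantom(inv, rigid = tf)
  fit <- estimateRigid(PairedLandmarks(inv$landmarks, ex$landmarks))
  expect_lt(rotationAngleDistance(rotation(fit),
                                  rotation(ex$truth$rigid)), 1e-6)
  expect_lt(max(abs(translation(fit) - translation(ex$truth$rigid))), 1e-6)

  # shrinkage scales pairwise distances
  exs <- makeExvivoPhantom(inv, rigid = tf, shrink = 0.95)
  d0 <- dist(pointCoords(inv$landmarks))
  d1 <- dist(pointCoords(exs$landmarks))
  expect_lt(max(abs(d1 / d0 - 0.95)), 1e-6)
  expect_error(makeExvivoPhantom(inv, rigid = tf, shrink = 0.5), "shrink")
})

test_that("section phantom at zero deformation and noise is the slice", {
  inv <- makeInvivoPhantom(seed = 4)
  sl <- extractSlice(inv$volume, 20)
  sec <- makeSectionPhantom(sl$data, sl$pixelSize, amplitudeMm = 0,
                            noiseSigmaMm = 0, seed = 5)
  expect_equal(volData(sec$section)[, ], sl$data, tolerance = 1e-9)
  r <- runTREProtocol(sec$pairs, nIter = 10, seed = 6)
  expect_lt(max(r@distances), 1e-9)

  sec2 <- makeSectionPhantom(sl$data, sl$pixelSize, amplitudeMm = 0,
                             noiseSigmaMm = 0, seed = 5)
  expect_identical(pointCoords(sourceSet(sec2$pairs)),
                   pointCoords(sourceSet(sec$pairs)))
})

test_that("affine-family deformations are recovered exactly by the protocol", {
  inv <- makeInvivoPhantom(seed = 7)
  sl <- extractSlice(inv$volume, 18)
  sec <- makeSectionPhantom(sl$data, sl$pixelSize, amplitudeMm = 3,
                            deformation = "affine", noiseSigmaMm = 0,
                            seed = 8)
  # the deformation really moves points by up to the requested amplitude
  mri <- pointCoords(targetSet(sec$pairs))
  hist <- pointCoords(sourceSet(sec$pairs))
  expect_gt(max(sqrt(rowSums((hist - mri)^2))), 1)
  r <- runTREProtocol(sec$pairs, nIter = 100, seed = 9)
  expect_lt(median(r@distances), 1e-6)
})

test_that("generic TPS deformations are recovered only approximately", {
  inv <- makeInvivoPhantom(seed = 10)
  sl <- extractSlice(inv$volume, 20)
  sec <- makeSectionPhantom(sl$data, sl$pixelSize, amplitudeMm = 3,
                            deformation = "tps", noiseSigmaMm = 0,
                            seed = 11)
  r <- runTREProtocol(sec$pairs, nIter = 30, seed = 12)
  med <- median(r@distances)
  expect_gt(med, 1e-6)   # out of the span of any half-split refit
  expect_lt(med, 3)      # but far below the deformation amplitude
})

test_that("map stack phantom reproduces its generator statistics", {
  inv <- makeInvivoPhantom(radiiMm = c(15, 13, 11), seed = 13)
  # sd = 0: region statistics return the generator means exactly
  p0 <- habitatReferenceParams()
  p0$sd[] <- 0
  ms0 <- makeMapStack(inv$roi, params = p0, seed = 14)
  rs0 <- regionStats(ms0$stack, ms0$habitatLabels)
  for (i in seq_len(nrow(rs0))) {
    h <- match(rs0$region[i], LETTERS)
    expect_equal(rs0$mean[i], p0$mean[h, rs0$channel[i]])
    expect_equal(rs0$sd[i], 0)
  }
  expect_equal(ms0$nClipped, 0L)

  # reference SDs at ~500 voxels/habitat: sample moments match the clipped
  # normal the generator draws from, within 3 SE
  ms <- makeMapStack(inv$roi, seed = 15)
  expect_true(all(table(volData(ms$habitatLabels)[
    volData(ms$habitatLabels) > 0]) >= 300))
  rs <- regionStats(ms$stack, ms$habitatLabels)
  p <- habitatReferenceParams()
  clippedMoments <- function(mu, sg) {
    if (sg == 0) return(c(mean = mu, sd = 0))
    a <- mu / sg
    m1 <- mu * pnorm(a) + sg * dnorm(a)
    m2 <- (mu^2 + sg^2) * pnorm(a) + mu * sg * dnorm(a)
    c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
  }
  worstZ <- 0
  for (i in seq_len(nrow(rs))) {
    h <- match(rs$region[i], LETTERS)
    cm <- clippedMoments(p$mean[h, rs$channel[i]], p$sd[h, rs$channel[i]])
    z <- (rs$mean[i] - cm["mean"]) / (cm["sd"] / sqrt(rs$n_voxels[i]))
    worstZ <- max(worstZ, abs(z))
  }
  expect_lt(worstZ, 3)
  expect_gt(ms$nClipped, 0L)
})

test_that("habitat clustering recovers the phantom partition", {
  inv <- makeInvivoPhantom(seed = 16)
  ms <- makeMapStack(inv$roi, seed = 17)
  cr <- clusterHabitats(ms$stack, k = 4, seed = 18)
  roiv <- volData(roiMask(ms$stack)) > 0
  ari <- clusterAgreement(volData(ms$habitatLabels)[roiv],
                          volData(cr@labels)[roiv])
  # substantial recovery; the overlap of the reference habitat
  # distributions caps agreement near 0.8
  expect_gt(ari, 0.7)
  # stable under the clustering seed
  cr2 <- clusterHabitats(ms$stack, k = 4, seed = 19)
  expect_gt(clusterAgreement(volData(cr@labels)[roiv],
                             volData(cr2@labels)[roiv]), 0.98)
})
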