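test_that("exact recovery of constructed rigid transforms", {
  src <- randomLandmarks3D(12, seed = 1)
  # identity
  fit0 <- estimateRigid(PairedLandmarks(src, src))
  expect_lt(rotationAngleDistance(rotation(fit0)), 1e-12)
  expect_lt(max(abs(translation(fit0))), 1e-12)
  expect_equal(fit0@rmsResidual, 0, tolerance = 1e-12)

  # 90 degrees about z plus translation (5, 0, 0)
  tf <- RigidTransform(rotationAboutAxis(c(0, 0, 1), pi / 2), c(5, 0, 0))
  tgt <- applyRigid(tf, src)
  fit <- estimateRigid(PairedLandmarks(src, tgt))
  expect_lt(rotationAngleDistance(rotation(fit), rotation(tf)), 1e-9)
  expect_lt(max(abs(translation(fit) - translation(tf))), 1e-9)
})

test_that("noisy fit matches a brute-force small-angle refinement oracle", {
  src <- randomLandmarks3D(40, seed = 2)
  truth <- randomRigidTransform(seed = 3, maxAngleDeg = 25)
  sigma <- 0.5
  withr::with_seed(4, {
    noisy <- pointCoords(applyRigid(truth, src)) +
      matrix(rnorm(120, 0, sigma), 40, 3)
  })
  tgt <- LandmarkSet(noisy, labels = pointLabels(src), spaceName = "in_vivo")
  fit <- estimateRigid(PairedLandmarks(src, tgt))
  expect_lt(rotationAngleDistance(rotation(fit), rotation(truth)),
            2 * pi / 180)
  expect_equal(det(rotation(fit)), 1, tolerance = 1e-9)

  # oracle: exhaustive small-angle grid around the noiseless truth, with the
  # optimal translation (centroid match) closed-form per candidate rotation
  X <- pointCoords(src); Y <- noisy
  cx <- colMeans(X); cy <- colMeans(Y)
  ssdFor <- function(R) {
    tr <- cy - drop(R %*% cx)
    sum((sweep(X %*% t(R), 2, tr, "+") - Y)^2)
  }
  best <- list(ssd = Inf, R = NULL)
  grid <- seq(-1.5, 1.5, by = 0.25) * pi / 180
  for (ax in grid) for (ay in grid) for (az in grid) {
    R <- quaternionRotation(c(1, 0, 0), ax) %*%
         quaternionRotation(c(0, 1, 0), ay) %*%
         quaternionRotation(c(0, 0, 1), az) %*% rotation(truth)
    s <- ssdFor(R)
    if (s < best$ssd) best <- list(ssd = s, R = R)
  }
  # the closed-form fit must be at least as good as the oracle's best grid
  # point and lie within one grid step of it
  expect_lte(ssdFor(rotation(fit)), best$ssd + 1e-9)
  expect_lt(rotationAngleDistance(rotation(fit), best$R), 0.6 * pi / 180)
  # rms residual reflects the injected noise level (3 coordinates per point)
  expect_gt(fit@rmsResidual, 0.6 * sigma)
  expect_lt(fit@rmsResidual, 2.2 * sigma)
})

test_that("degenerate configurations are rejected by name", {
  a <- LandmarkSet(matrix(1:6, 2, 3))
  expect_error(estimateRigid(PairedLandmarks(a, a)), "at least 3")
  line <- LandmarkSet(cbind(1:5, 2 * (1:5), 3 * (1:5)))
  expect_error(estimateRigid(PairedLandmarks(line, line)), "collinear")
})

test_that("reflective least-squares optima are corrected to det +1", {
  src <- randomLandmarks3D(15, seed = 5)
  mirrored <- pointCoords(src) %*% diag(c(-1, 1, 1))
  tgt <- LandmarkSet(mirrored, labels = pointLabels(src))
  fit <- estimateRigid(PairedLandmarks(src, tgt))
  expect_equal(det(rotation(fit)), 1, tolerance = 1e-9)
})

test_that("rms residual is invariant to pair ordering", {
  src <- randomLandmarks3D(20, seed = 6)
  truth <- randomRigidTransform(seed = 7)
  withr::with_seed(8, {
    tgt <- LandmarkSet(pointCoords(applyRigid(truth, src)) +
                         matrix(rnorm(60, 0, 1), 20, 3),
                       labels = pointLabels(src))
    perm <- sample(20)
  })
  f1 <- estimateRigid(PairedLandmarks(src, tgt))
  srcP <- LandmarkSet(pointCoords(src)[perm, ],
                      labels = pointLabels(src)[perm])
  f2 <- estimateRigid(PairedLandmarks(srcP, tgt))
  expect_equal(f1@rmsResidual, f2@rmsResidual, tolerance = 1e-12)
})

test_that("applyRigid maps points and volumes consistently", {
  lm <- LandmarkSet(rbind(c(1, 2, 3)), labels = "p")
  shift <- RigidTransform(translation = c(1, 1, 1))
  expect_equal(unname(pointCoords(applyRigid(shift, lm))[1, ]), c(2, 3, 4))
  expect_equal(pointCoords(applyRigid(RigidTransform(), lm)),
               pointCoords(lm))

  # volume: rotate forward then back about the grid centre; interpolation
  # error on a smooth field stays well under 2% of the dynamic range
  dm <- c(36, 36, 28); sp <- c(1.5, 1.5, 2)
  withr::with_seed(9, {
    arr <- HistoMRIfuse:::.smooth3d(array(rnorm(prod(dm)), dm), 3)
  })
  arr <- arr / max(abs(arr))
  v <- Volume(arr, spacing = sp)
  ctr <- (dm - 1) * sp / 2
  R <- rotationAboutAxis(c(1, 1, 0) / sqrt(2), 0.3)
  tf <- RigidTransform(R, ctr - drop(R %*% ctr))
  back <- applyRigid(invertRigid(tf), applyRigid(tf, v))
  crop <- function(a) a[9:28, 9:28, 7:22]
  err <- mean(abs(crop(volData(back)) - crop(arr)))
  expect_lt(err / diff(range(crop(arr))), 0.02)
})

test_that("composition acts as sequential application and inverts cleanly", {
  t1 <- randomRigidTransform(seed = 10)
  t2 <- randomRigidTransform(seed = 11)
  withr::with_seed(12, pts <- matrix(runif(300, -40, 40), 100, 3))
  lm <- LandmarkSet(pts)
  seq2 <- applyRigid(t1, applyRigid(t2, lm))
  comp <- applyRigid(composeRigid(t1, t2), lm)
  expect_lt(max(abs(pointCoords(seq2) - pointCoords(comp))), 1e-9)

  idl <- composeRigid(t1, invertRigid(t1))
  expect_lt(rotationAngleDistance(rotation(idl)), 1e-9)
  expect_lt(max(abs(translation(idl))), 1e-9)

  z30 <- RigidTransform(rotationAboutAxis(c(0, 0, 1), pi / 6))
  z60 <- RigidTransform(rotationAboutAxis(c(0, 0, 1), pi / 3))
  expect_lt(max(abs(rotation(composeRigid(z30, z60)) -
                      rotationAboutAxis(c(0, 0, 1), pi / 2))), 1e-12)
})
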