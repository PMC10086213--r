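smallStack <- function(nROI = 10, seed = 51, dims = c(5, 5, 4)) {
  withr::with_seed(seed, {
    roiArr <- array(0, dims)
    roiArr[sample(prod(dims), nROI)] <- 1
    chans <- setNames(lapply(channelNames(), function(nm)
      Volume(array(rnorm(prod(dims), 10, 2), dims))), channelNames())
  })
  list(stack = ParametricMapStack(chans, Volume(roiArr)),
       roiArr = roiArr)
}

test_that("feature extraction indexes ROI voxels faithfully", {
  s <- smallStack(10)
  fx <- extractFeatures(s$stack)
  expect_equal(dim(fx$features), c(10L, 8L))
  expect_identical(colnames(fx$features), channelNames())
  # indexing oracle: row v equals the 8 channel values at that voxel
  for (r in c(1, 5, 10)) {
    v <- fx$voxelIndices[r]
    expect_equal(unname(fx$features[r, ]),
                 sapply(mapChannels(s$stack), function(ch) volData(ch)[v]),
                 ignore_attr = TRUE)
  }

  # a voxel with NaN ADC is dropped and counted
  s2 <- smallStack(10, seed = 52)
  ch <- mapChannels(s2$stack)
  arr <- volData(ch$ADC)
  arr[which(s2$roiArr > 0)[3]] <- NaN
  ch$ADC <- Volume(arr)
  st2 <- ParametricMapStack(ch, roiMask(s2$stack))
  expect_message(fx2 <- extractFeatures(st2), "dropped")
  expect_equal(nrow(fx2$features), 9L)
  expect_equal(fx2$nDropped, 1L)

  # all-NaN channel and empty ROI are errors
  arr[s2$roiArr > 0] <- NaN
  ch$ADC <- Volume(arr)
  expect_error(extractFeatures(ParametricMapStack(ch, roiMask(s2$stack))),
               "ADC")
  empty <- ParametricMapStack(mapChannels(s$stack),
                              Volume(array(0, c(5, 5, 4))))
  expect_error(extractFeatures(empty), "empty ROI")
})

test_that("standardization z-scores, inverts and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  z <- standardizeFeatures(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1))
  z2 <- standardizeFeatures(unclass(z))
  expect_lt(max(abs(unclass(z2) - unclass(z))), 1e-12)
  back <- destandardizeFeatures(unclass(z), z)
  expect_lt(max(abs(back - m)), 1e-10)
  bad <- cbind(a = c(1, 2, 3), kep = c(5, 5, 5))
  expect_error(standardizeFeatures(bad), "kep")
})

test_that("k-means separates point clouds and is seed-deterministic", {
  withr::with_seed(53, {
    x <- rbind(matrix(rnorm(200 * 3), 200, 3),
               matrix(rnorm(150 * 3, 100), 150, 3))
  })
  km <- kmeansCluster(x, k = 2, seed = 1, nRestarts = 5)
  expect_equal(length(unique(km$assignments[1:200])), 1L)
  expect_equal(length(unique(km$assignments[201:350])), 1L)
  withinScatter <- sum(scale(x[1:200, ], scale = FALSE)^2) +
    sum(scale(x[201:350, ], scale = FALSE)^2)
  expect_equal(km$inertia, withinScatter, tolerance = 1e-9)

  km2 <- kmeansCluster(x, k = 2, seed = 1, nRestarts = 5)
  expect_identical(km$assignments, km2$assignments)

  small <- x[1:6, ]
  expect_equal(kmeansCluster(small, k = 6, seed = 1)$inertia, 0)
  expect_error(kmeansCluster(small, k = 7, seed = 1), "exceeds")
  expect_error(kmeansCluster(small, k = 1, seed = 1), ">= 2")
})

test_that("labels map back onto the grid and re-extract identically", {
  s <- smallStack(30, seed = 54, dims = c(6, 6, 5))
  fx <- extractFeatures(s$stack)
  km <- kmeansCluster(standardizeFeatures(fx$features), k = 3, seed = 2)
  lab <- mapLabels(km$assignments, fx$voxelIndices, roiMask(s$stack))
  arr <- volData(lab)
  expect_true(all(arr[s$roiArr == 0] == 0))
  expect_true(all(arr[s$roiArr > 0] %in% 1:3))
  # renumbering is by descending size
  sizes <- table(arr[arr > 0])
  expect_true(all(diff(as.integer(sizes)) <= 0))
  # round trip: re-extracted labels are a consistent relabeling
  again <- arr[fx$voxelIndices]
  expect_equal(clusterAgreement(again, km$assignments), 1)

  one <- mapLabels(rep(1L, length(fx$voxelIndices)), fx$voxelIndices,
                   roiMask(s$stack))
  expect_setequal(unique(volData(one)[s$roiArr > 0]), 1)
})

test_that("region statistics match hand arithmetic and flag tiny regions", {
  dims <- c(3, 3, 1)
  roi <- Volume(array(c(1, 1, 1, 0, 0, 0, 0, 0, 0), dims))
  lab <- Volume(array(c(1, 1, 2, 0, 0, 0, 0, 0, 0), dims))
  chans <- setNames(lapply(channelNames(), function(nm)
    Volume(array(0, dims))), channelNames())
  ktr <- array(0, dims); ktr[1:3] <- c(300, 320, 55)
  chans$Ktrans <- Volume(ktr)
  st <- ParametricMapStack(chans, roi)
  rs <- regionStats(st, lab)
  rowA <- rs[rs$region == "A" & rs$channel == "Ktrans", ]
  expect_equal(rowA$mean, 310)
  expect_equal(rowA$sd, sd(c(300, 320)), tolerance = 1e-9)
  rowB <- rs[rs$region == "B" & rs$channel == "Ktrans", ]
  expect_equal(rowB$sd, 0)
  expect_true(rowB$flagged)
  expect_equal(rowB$n_voxels, 1L)
})

test_that("region comparisons match brute-force sums of squares", {
  # 3 groups of 3 values: classic one-way ANOVA by hand
  g <- list(c(1, 2, 3), c(2, 3, 4), c(6, 7, 8))
  grand <- mean(unlist(g))
  ssb <- sum(sapply(g, function(x) 3 * (mean(x) - grand)^2))
  ssw <- sum(sapply(g, function(x) sum((x - mean(x))^2)))
  handF <- (ssb / 2) / (ssw / 6)

  dims <- c(3, 3, 1)
  roi <- Volume(array(1, dims))
  lab <- Volume(array(rep(1:3, each = 3), dims))
  chans <- setNames(lapply(channelNames(), function(nm)
    Volume(array(unlist(g), dims))), channelNames())
  st <- ParametricMapStack(chans, roi)
  cmp <- compareRegions(st, lab, pooledVariance = TRUE)
  expect_equal(cmp$anova$F[cmp$anova$channel == "ADC"], handF,
               tolerance = 1e-9)
  # Holm adjustment: never below raw, monotone in raw
  expect_true(all(cmp$pairwise$p_holm >= cmp$pairwise$p_raw - 1e-15))
  for (nm in unique(cmp$pairwise$channel)) {
    pc <- cmp$pairwise[cmp$pairwise$channel == nm, ]
    expect_true(all(diff(pc$p_holm[order(pc$p_raw)]) >= -1e-15))
  }
})

test_that("identical regions are non-significant, separated ones are", {
  dims <- c(10, 10, 2)
  withr::with_seed(55, vals <- rnorm(100, 50, 5))
  roi <- Volume(array(1, dims))
  lab <- Volume(array(rep(1:2, each = 100), dims))
  sameArr <- array(c(vals, vals), dims)
  chansSame <- setNames(lapply(channelNames(), function(nm)
    Volume(sameArr)), channelNames())
  cmpSame <- compareRegions(ParametricMapStack(chansSame, roi), lab)
  expect_true(all(cmpSame$pairwise$stars == "ns"))
  expect_true(all(cmpSame$anova$p > 0.99))

  farArr <- array(c(vals, vals + 50), dims)  # 10 pooled SDs apart
  chansFar <- setNames(lapply(channelNames(), function(nm)
    Volume(farArr)), channelNames())
  cmpFar <- compareRegions(ParametricMapStack(chansFar, roi), lab)
  expect_true(all(cmpFar$pairwise$p_holm < 1e-4))
  expect_true(all(cmpFar$pairwise$stars == "****"))
})

test_that("adjusted Rand index matches brute-force pair counting", {
  ariBrute <- function(a, b) {
    n <- length(a)
    sameA <- outer(a, a, "==")[upper.tri(diag(n))]
    sameB <- outer(b, b, "==")[upper.tri(diag(n))]
    n11 <- sum(sameA & sameB); n00 <- sum(!sameA & !sameB)
    n10 <- sum(sameA & !sameB); n01 <- sum(!sameA & sameB)
    ri <- (n11 + n00) / choose(n, 2)
    expRI <- ((n11 + n10) * (n11 + n01) + (n00 + n10) * (n00 + n01)) /
      choose(n, 2)^2
    (ri - expRI) / (1 - expRI)
  }
  withr::with_seed(56, {
    for (i in 1:10) {
      a <- sample(1:3, 25, replace = TRUE)
      b <- sample(1:3, 25, replace = TRUE)
      expect_equal(clusterAgreement(a, b), ariBrute(a, b),
                   tolerance = 1e-12)
    }
  })
  a <- rep(1:4, each = 5)
  expect_equal(clusterAgreement(a, a), 1)
  perm <- c(3, 1, 4, 2)[a]
  expect_equal(clusterAgreement(a, perm), 1)
  skip_if_not_installed("mclust")
  withr::with_seed(57, {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:5, 60, replace = TRUE)
  })
  expect_equal(clusterAgreement(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("clustering is invariant to channel order and voxel shuffling", {
  withr::with_seed(58, {
    x <- rbind(matrix(rnorm(300 * 8, 0), 300, 8),
               matrix(rnorm(300 * 8, 4), 300, 8),
               matrix(rnorm(300 * 8, -4), 300, 8))
    colnames(x) <- channelNames()
    perm <- sample(nrow(x))
  })
  z <- standardizeFeatures(x)
  k1 <- kmeansCluster(z, k = 3, seed = 9)
  k2 <- kmeansCluster(z[, c(3, 1, 8, 5, 2, 7, 4, 6)], k = 3, seed = 10)
  expect_equal(clusterAgreement(k1$assignments, k2$assignments), 1)
  k3 <- kmeansCluster(z[perm, ], k = 3, seed = 11)
  expect_equal(clusterAgreement(k1$assignments[perm], k3$assignments), 1)
})
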