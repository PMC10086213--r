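makePairs2D <- function(n = 40, seed = 41, extent = 60, offset = c(0, 0)) {
  withr::with_seed(seed, src <- matrix(runif(2 * n, 0, extent), n, 2))
  PairedLandmarks(LandmarkSet(src, spaceName = "histology"),
                  LandmarkSet(sweep(src, 2, offset, "+"),
                              labels = rownames(src),
                              spaceName = "ex_vivo_2"))
}

test_that("random splits are disjoint, exhaustive and reproducible", {
  pairs <- makePairs2D(40)
  sp <- splitLandmarks(pairs, 0.5, seed = 1)
  expect_equal(length(sp$reg), 20L)
  expect_equal(length(sp$eval), 20L)
  expect_length(intersect(pointLabels(sourceSet(sp$reg)),
                          pointLabels(sourceSet(sp$eval))), 0)
  expect_setequal(c(pointLabels(sourceSet(sp$reg)),
                    pointLabels(sourceSet(sp$eval))),
                  pointLabels(sourceSet(pairs)))
  sp2 <- splitLandmarks(pairs, 0.5, seed = 1)
  expect_identical(pointLabels(sourceSet(sp2$reg)),
                   pointLabels(sourceSet(sp$reg)))

  # odd count at fraction 0.5: registration set gets the extra point
  odd <- makePairs2D(39)
  spo <- splitLandmarks(odd, 0.5, seed = 2)
  expect_equal(length(spo$reg), 20L)
  expect_error(splitLandmarks(makePairs2D(5), 0.5, 1), "at least 6")
  expect_error(splitLandmarks(pairs, 0.05, 1), "fewer than 3")
})

test_that("each landmark lands in the evaluation set half the time", {
  pairs <- makePairs2D(10)
  counts <- integer(10)
  for (s in 1:1000) {
    sp <- splitLandmarks(pairs, 0.5, seed = s)
    idx <- match(pointLabels(sourceSet(sp$eval)),
                 pointLabels(sourceSet(pairs)))
    counts[idx] <- counts[idx] + 1L
  }
  expect_true(all(abs(counts / 1000 - 0.5) < 0.05))
})

test_that("protocol yields zero TRE within the recoverable model class", {
  # source == target
  same <- makePairs2D(36, seed = 42)
  r0 <- runTREProtocol(same, nIter = 20, seed = 1)
  expect_lt(max(r0@distances), 1e-9)
  expect_equal(r0@nAborted, 0L)

  # constant offset: reproduced by the TPS affine part from any subset
  off <- makePairs2D(36, seed = 43, offset = c(3, 4))
  r1 <- runTREProtocol(off, nIter = 20, seed = 1)
  expect_lt(max(r1@distances), 1e-9)

  # pooled distances are invariant to a global translation of both sets
  shifted <- PairedLandmarks(
    LandmarkSet(pointCoords(sourceSet(off)) + 100,
                labels = pointLabels(sourceSet(off))),
    LandmarkSet(pointCoords(targetSet(off)) + 100,
                labels = pointLabels(sourceSet(off))))
  r2 <- runTREProtocol(shifted, nIter = 20, seed = 1)
  expect_equal(r2@distances, r1@distances, tolerance = 1e-6)

  # reproducibility under the seed
  r3 <- runTREProtocol(off, nIter = 20, seed = 1)
  expect_identical(r3@distances, r1@distances)
})

test_that("summaries match hand-computable and distributional values", {
  s <- summarizeTRE(c(1, 2, 3, 4, 5))
  expect_equal(s$median_mm, 3)
  expect_equal(s$iqr_mm, 2)
  expect_equal(s$mean_mm, 3)
  s1 <- summarizeTRE(2.5)
  expect_equal(s1$median_mm, 2.5)
  expect_equal(s1$iqr_mm, 0)
  expect_equal(s1$sd_mm, 0)
  expect_error(summarizeTRE(numeric(0)), "no distances")

  # Rayleigh sample: median within 2% of sigma * sqrt(2 log 2)
  sigma <- 1.7
  withr::with_seed(44, ray <- sigma * sqrt(-2 * log(runif(10000))))
  expect_lt(abs(summarizeTRE(ray)$median_mm / (sigma * sqrt(2 * log(2))) - 1),
            0.02)
})

test_that("TRE per volume matches the worked example and inverts", {
  expect_equal(trePerVolume(2.145, 165.0), 0.013)
  expect_equal(trePerVolume(0, 123), 0)
  expect_error(trePerVolume(1, 0), "positive")
  expect_error(trePerVolume(-1, 10), "non-negative")
  # ratio * volume recovers the TRE within rounding of the 3rd decimal
  expect_lt(abs(trePerVolume(2.145, 165) * 165 - 2.145), 165 * 5e-4)
})

test_that("group comparisons match hand-computed rank statistics", {
  # Kruskal-Wallis H on {1,2,3} vs {4,5,6}:
  # H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1) with rank sums 6 and 15
  hand <- 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7
  cmp <- compareTREGroups(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(cmp$kruskal$H, hand, tolerance = 1e-12)
  # exact rank-sum p for the most extreme arrangement: 2 / choose(6,3)
  expect_equal(cmp$pairwise$p_raw, 2 / choose(6, 3), tolerance = 1e-12)

  # identical groups: nothing significant
  g <- c(1.2, 3.4, 2.2, 4.1, 0.8)
  same <- compareTREGroups(list(a = g, b = g, c = g))
  expect_true(all(!same$pairwise$significant))
  expect_gt(same$kruskal$p, 0.05)

  # strong separation: Bonferroni-adjusted p below 0.001 at n = 50
  withr::with_seed(45, {
    x <- rnorm(50); y <- rnorm(50) + 10
  })
  far <- compareTREGroups(list(x = x, y = y))
  expect_lt(far$pairwise$p_bonferroni, 0.001)
  expect_error(compareTREGroups(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("TRE results serialize with per-distance metadata", {
  pairs <- makePairs2D(36, seed = 46, offset = c(1, 1))
  r <- runTREProtocol(pairs, nIter = 5, seed = 3,
                      pairKind = "histology_exvivo",
                      sectionLevel = "middle", patientId = "p1")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTREDistances(r, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), length(r@distances))
  expect_setequal(unique(tab$iteration), 1:5)
  expect_equal(unique(tab$pair_kind), "histology_exvivo")
})
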