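## Voxel-wise k-means habitat clustering of the eight co-registered
## quantitative parametric maps within the tumor ROI. Channels are made
## commensurable by per-channel z-scoring ("equal weighting"); clustering
## uses feature values only — never voxel coordinates — and the resulting
## labels are mapped back onto the anatomical grid for display.

#' Extract the voxel-by-channel feature matrix from a map stack
#'
#' One row per ROI voxel, eight columns in the canonical channel order;
#' rows containing non-finite values are dropped and counted. Linear voxel
#' indices are retained for back-mapping labels onto the grid.
#'
#' @param stack A \linkS4class{ParametricMapStack} with a non-empty ROI.
#' @return A list with \code{features} (n x 8 matrix), \code{voxelIndices}
#'   (linear indices into the grid), and \code{nDropped}.
#' @export
extractFeatures <- function(stack) {
  stopifnot(is(stack, "ParametricMapStack"))
  roiIdx <- which(stack@roi@data > 0)
  if (length(roiIdx) == 0L) stop("empty ROI")
  feats <- vapply(stack@channels, function(v) v@data[roiIdx],
                  numeric(length(roiIdx)))
  colnames(feats) <- names(stack@channels)
  allNA <- colSums(is.finite(feats)) == 0L
  if (any(allNA))
    stop("channel(s) with no finite ROI values: ",
         paste(colnames(feats)[allNA], collapse = ", "))
  ok <- rowSums(!is.finite(feats)) == 0L
  nDropped <- sum(!ok)
  if (nDropped > 0L)
    message(nDropped, " ROI voxel(s) dropped for non-finite values")
  list(features = feats[ok, , drop = FALSE], voxelIndices = roiIdx[ok],
       nDropped = nDropped)
}

#' Standardize features to zero mean and unit SD per channel
#'
#' Implements the equal weighting of channels with wildly different native
#' units. The centering/scaling parameters are kept as attributes so
#' cluster centroids can be mapped back to native units with
#' \code{destandardizeFeatures}.
#'
#' @param features n x p numeric matrix (n >= 2).
#' @param standardized Matrix (e.g. of centroids) in standardized units.
#' @param scaling A standardized matrix carrying the scaling attributes, or
#'   a list with \code{center} and \code{scale}.
#' @return \code{standardizeFeatures}: the z-scored matrix with attributes
#'   \code{center} and \code{scale}; \code{destandardizeFeatures}: the
#'   matrix in native units.
#' @export
standardizeFeatures <- function(features) {
  if (nrow(features) < 2L) stop("need at least 2 rows to standardize")
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  bad <- scl <= 0 | !is.finite(scl)
  if (any(bad))
    stop("zero-variance channel(s): ",
         paste(colnames(features)[bad], collapse = ", "))
  out <- scale(features, center = ctr, scale = scl)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' @rdname standardizeFeatures
#' @export
destandardizeFeatures <- function(standardized, scaling = standardized) {
  ctr <- if (is.list(scaling)) scaling$center else attr(scaling, "center")
  scl <- if (is.list(scaling)) scaling$scale else attr(scaling, "scale")
  if (is.null(ctr) || is.null(scl)) stop("scaling parameters not found")
  sweep(sweep(unclass(standardized), 2L, scl, "*"), 2L, ctr, "+")
}

## k-means++ initial centres (Arthur & Vassilvitskii seeding)
.kmeansPlusPlusInit <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1, ])^2)
  for (i in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    centers[i, ] <- x[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[i, ])^2))
  }
  centers
}

#' k-means clustering of voxel features
#'
#' Lloyd's algorithm with k-means++ seeding, repeated \code{nRestarts}
#' times; the solution with the lowest total within-cluster sum of squares
#' (inertia) is kept. All randomness derives from \code{seed}. Spatial
#' coordinates are never part of the features.
#'
#' @param features n x p matrix (typically standardized; n >= k).
#' @param k Number of clusters (default 4, >= 2).
#' @param seed Integer RNG seed.
#' @param nRestarts Number of k-means++ restarts (default 10).
#' @return A list with \code{assignments} (1..k per row), \code{centers}
#'   (k x p), \code{inertia}, \code{k}, \code{seed}.
#' @export
kmeansCluster <- function(features, k = 4L, seed = 1L, nRestarts = 10L) {
  features <- unclass(as.matrix(features))
  n <- nrow(features)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of voxels (", n, ")")
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(nRestarts)) {
      init <- .kmeansPlusPlusInit(features, k)
      fit <- tryCatch(
        stats::kmeans(features, centers = init, iter.max = 100L,
                      algorithm = "Lloyd"),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss)
        best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed on every restart")
  list(assignments = as.integer(best$cluster), centers = best$centers,
       inertia = best$tot.withinss, k = as.integer(k),
       seed = as.integer(seed))
}

#' Map cluster assignments back onto the anatomical grid
#'
#' Produces a label volume on the reference grid: 0 outside the ROI, 1..k
#' inside, with clusters renumbered deterministically by descending size.
#'
#' @param assignments Integer cluster per feature row (1..k).
#' @param voxelIndices Linear grid indices of the feature rows (from
#'   \code{\link{extractFeatures}}).
#' @param reference \linkS4class{Volume} defining the output grid (e.g. the
#'   anatomical T2w volume the habitats are displayed on).
#' @param centers Optional k x p centroid matrix, reordered consistently
#'   and returned in the \code{"centers"} attribute.
#' @return A label \linkS4class{Volume}; renumbered centroids (if given)
#'   in the \code{"centers"} attribute.
#' @export
mapLabels <- function(assignments, voxelIndices, reference, centers = NULL) {
  stopifnot(is(reference, "Volume"))
  if (length(assignments) != length(voxelIndices))
    stop("assignments and voxelIndices must have equal length")
  if (max(voxelIndices) > length(reference@data))
    stop("voxel indices exceed the reference grid")
  sizes <- table(assignments)
  k <- max(assignments)
  ord <- order(as.integer(sizes), decreasing = TRUE)
  old <- as.integer(names(sizes))[ord]
  remap <- integer(k)
  remap[old] <- seq_along(old)
  lab <- array(0, dim(reference@data))
  lab[voxelIndices] <- remap[assignments]
  out <- Volume(lab, spacing = reference@spacing, origin = reference@origin,
                direction = reference@direction,
                spaceName = reference@spaceName)
  if (!is.null(centers))
    attr(out, "centers") <- centers[old, , drop = FALSE]
  out
}

#' Cluster a parametric map stack into tumor habitats
#'
#' Convenience pipeline: \code{\link{extractFeatures}} ->
#' \code{\link{standardizeFeatures}} -> \code{\link{kmeansCluster}} ->
#' \code{\link{mapLabels}}.
#'
#' @param stack A \linkS4class{ParametricMapStack}.
#' @param k Number of habitats (default 4).
#' @param seed Integer RNG seed.
#' @param nRestarts k-means++ restarts (default 10).
#' @return A \linkS4class{ClusterResult}; the \code{featureMeans} slot holds
#'   the (size-ordered) centroids in standardized units, with the native
#'   scaling parameters in the \code{"center"}/\code{"scale"} attributes of
#'   the slot matrix.
#' @export
clusterHabitats <- function(stack, k = 4L, seed = 1L, nRestarts = 10L) {
  fx <- extractFeatures(stack)
  z <- standardizeFeatures(fx$features)
  km <- kmeansCluster(z, k = k, seed = seed, nRestarts = nRestarts)
  lab <- mapLabels(km$assignments, fx$voxelIndices, stack@roi,
                   centers = km$centers)
  centers <- attr(lab, "centers")
  attr(lab, "centers") <- NULL
  attr(centers, "center") <- attr(z, "center")
  attr(centers, "scale") <- attr(z, "scale")
  new("ClusterResult", labels = lab, k = as.integer(k),
      featureMeans = centers, channelOrder = colnames(fx$features),
      seed = as.integer(seed), inertia = km$inertia)
}

#' Per-habitat statistics of the native-unit parametric maps
#'
#' Mean, SD and voxel count per region per channel in native units. A
#' region with fewer than 2 voxels gets SD 0 and a flag.
#'
#' @param stack A \linkS4class{ParametricMapStack}.
#' @param labels Label \linkS4class{Volume} (0 outside, 1..k inside) or a
#'   \linkS4class{ClusterResult}.
#' @return data.frame with columns \code{region}, \code{channel},
#'   \code{mean}, \code{sd}, \code{n_voxels}, \code{flagged}, \code{unit}.
#' @export
regionStats <- function(stack, labels) {
  stopifnot(is(stack, "ParametricMapStack"))
  if (is(labels, "ClusterResult")) labels <- labels@labels
  if (!identical(dim(labels@data), dim(stack@roi@data)))
    stop("label grid does not match the stack grid")
  lab <- labels@data
  regions <- sort(unique(lab[lab > 0]))
  out <- list()
  for (reg in regions) {
    idx <- which(lab == reg)
    for (nm in names(stack@channels)) {
      v <- stack@channels[[nm]]@data[idx]
      v <- v[is.finite(v)]
      flagged <- length(v) < 2L
      out[[length(out) + 1L]] <- data.frame(
        region = LETTERS[reg], channel = nm, mean = mean(v),
        sd = if (flagged) 0 else stats::sd(v),
        n_voxels = length(v), flagged = flagged,
        unit = unname(stack@units[nm]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare parametric values across habitats
#'
#' Per channel: one-way ANOVA (F, p) across regions, then all pairwise
#' two-sample t-tests (Welch by default; pooled variance available for
#' textbook cross-checks) with Holm-Bonferroni step-down adjustment and
#' significance stars at 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param stack A \linkS4class{ParametricMapStack}.
#' @param labels Label \linkS4class{Volume} or \linkS4class{ClusterResult}.
#' @param pooledVariance If TRUE use classic equal-variance t-tests.
#' @return A list with \code{anova} (data.frame: channel, F, df1, df2, p)
#'   and \code{pairwise} (data.frame: channel, region pair, raw and
#'   Holm-adjusted p, stars).
#' @export
compareRegions <- function(stack, labels, pooledVariance = FALSE) {
  stopifnot(is(stack, "ParametricMapStack"))
  if (is(labels, "ClusterResult")) labels <- labels@labels
  lab <- labels@data
  regions <- sort(unique(lab[lab > 0]))
  if (length(regions) < 2L) stop("need at least 2 regions")
  idxBy <- lapply(regions, function(r) which(lab == r))
  if (any(vapply(idxBy, length, 1L) < 2L))
    stop("every region needs at least 2 voxels")
  anovaOut <- list(); pwOut <- list()
  for (nm in names(stack@channels)) {
    vals <- lapply(idxBy, function(i) stack@channels[[nm]]@data[i])
    df <- data.frame(value = unlist(vals),
                     region = factor(rep(LETTERS[regions],
                                         vapply(vals, length, 1L))))
    av <- stats::anova(stats::aov(value ~ region, data = df))
    anovaOut[[nm]] <- data.frame(channel = nm, F = av$`F value`[1],
                                 df1 = av$Df[1], df2 = av$Df[2],
                                 p = av$`Pr(>F)`[1],
                                 stringsAsFactors = FALSE)
    cmb <- utils::combn(seq_along(regions), 2)
    praw <- apply(cmb, 2, function(ij)
      stats::t.test(vals[[ij[1]]], vals[[ij[2]]],
                    var.equal = pooledVariance)$p.value)
    padj <- stats::p.adjust(praw, method = "holm")
    pwOut[[nm]] <- data.frame(
      channel = nm, region1 = LETTERS[regions[cmb[1, ]]],
      region2 = LETTERS[regions[cmb[2, ]]], p_raw = praw, p_holm = padj,
      stars = .pStars(padj), stringsAsFactors = FALSE)
  }
  list(anova = do.call(rbind, c(anovaOut, make.row.names = FALSE)),
       pairwise = do.call(rbind, c(pwOut, make.row.names = FALSE)))
}

.pStars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the contingency table; 1 for identical partitions (up to
#' label permutation), ~0 for independent ones.
#'
#' @param a,b Integer/factor label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
clusterAgreement <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sumIJ <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expected <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)
  (sumIJ - expected) / (maxIdx - expected)
}

#' Write habitat region statistics as TSV
#'
#' Wide layout mirroring a per-region parameter table: one row per region,
#' one \code{mean +/- sd} column per channel.
#'
#' @param stats data.frame from \code{\link{regionStats}}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeRegionStats <- function(stats, path) {
  wide <- stats::reshape(
    transform(stats,
              cell = sprintf("%.1f ± %.1f", mean, sd))[,
              c("region", "channel", "cell")],
    idvar = "region", timevar = "channel", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  utils::write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
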