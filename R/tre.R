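## The accuracy protocol: landmarks are repeatedly split at random into a
## registration set and a disjoint evaluation set; an elastic (TPS) fit on
## the registration set is scored by the Euclidean target registration error
## (TRE) on the held-out landmarks, pooled over iterations.

.subsetPairs <- function(pairs, idx) {
  new("PairedLandmarks",
      source = new("LandmarkSet", spaceName = pairs@source@spaceName,
                   coords = pairs@source@coords[idx, , drop = FALSE]),
      target = new("LandmarkSet", spaceName = pairs@target@spaceName,
                   coords = pairs@target@coords[idx, , drop = FALSE]))
}

#' Randomly split paired landmarks into registration and evaluation sets
#'
#' The partition is disjoint and exhaustive; the registration set receives
#' \code{floor(fraction * n + 0.5)} pairs (so an odd count at fraction 0.5
#' gives the registration set the extra point) and is reproducible under the
#' seed.
#'
#' @param pairs \linkS4class{PairedLandmarks} with at least 6 pairs.
#' @param fraction Fraction assigned to the registration set (0 < f < 1).
#' @param seed Integer RNG seed.
#' @return A list with elements \code{reg} and \code{eval}, both
#'   \linkS4class{PairedLandmarks}.
#' @export
splitLandmarks <- function(pairs, fraction = 0.5, seed = 1L) {
  stopifnot(is(pairs, "PairedLandmarks"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n <- nrow(pairs@source@coords)
  if (n < 6L) stop("need at least 6 landmark pairs to split, got ", n)
  nReg <- floor(fraction * n + 0.5)
  if (nReg < 3L || n - nReg < 3L)
    stop("split leaves fewer than 3 landmarks in one set")
  idx <- withr::with_seed(seed, sample.int(n, nReg))
  list(reg = .subsetPairs(pairs, sort(idx)),
       eval = .subsetPairs(pairs, sort(setdiff(seq_len(n), idx))))
}

#' Run the repeated random-split TRE protocol
#'
#' Per iteration the landmark pairs are split at random, a thin-plate-spline
#' is fitted on the registration subset, the held-out source landmarks are
#' warped, and their Euclidean distances to the held-out targets are
#' recorded; distances from all iterations are pooled. Evaluation landmarks
#' are independent of the registration landmarks in every iteration
#' (asserted). Fit failures abort the affected iteration; more than 10\%
#' aborted iterations abort the protocol.
#'
#' @param pairs 2D \linkS4class{PairedLandmarks} (histology vs MRI section).
#' @param nIter Number of random-split iterations (default 100).
#' @param fraction Registration fraction per split (default 0.5).
#' @param lambda TPS regularization (default 0, pure interpolation).
#' @param seed Integer RNG seed; all randomness of the protocol derives
#'   from it.
#' @param pairKind,sectionLevel,patientId Metadata recorded in the result.
#' @return A \linkS4class{TREResult}.
#' @export
runTREProtocol <- function(pairs, nIter = 100L, fraction = 0.5, lambda = 0,
                           seed = 1L, pairKind = "histology_invivo",
                           sectionLevel = "unspecified",
                           patientId = "phantom") {
  stopifnot(is(pairs, "PairedLandmarks"))
  if (ncol(pairs@source@coords) != 2L)
    stop("the TRE protocol operates on 2D section landmarks")
  n <- nrow(pairs@source@coords)
  nReg <- floor(fraction * n + 0.5)
  if (n < 6L || nReg < 3L || n - nReg < 3L)
    stop("too few landmarks for the requested split")
  distances <- vector("list", nIter)
  iterOf <- vector("list", nIter)
  perIterMedian <- rep(NA_real_, nIter)
  nAborted <- 0L
  withr::with_seed(seed, {
    for (it in seq_len(nIter)) {
      regIdx <- sample.int(n, nReg)
      evalIdx <- setdiff(seq_len(n), regIdx)
      stopifnot(length(intersect(regIdx, evalIdx)) == 0L)
      d <- tryCatch({
        w <- fitTPS(.subsetPairs(pairs, regIdx), lambda = lambda)
        pred <- .tpsEvaluate(w, pairs@source@coords[evalIdx, , drop = FALSE])
        sqrt(rowSums((pred - pairs@target@coords[evalIdx, , drop = FALSE])^2))
      }, error = function(e) {
        message("iteration ", it, " aborted: ", conditionMessage(e))
        NULL
      })
      if (is.null(d)) { nAborted <- nAborted + 1L; next }
      distances[[it]] <- d
      iterOf[[it]] <- rep.int(it, length(d))
      perIterMedian[it] <- stats::median(d)
    }
  })
  if (nAborted > 0.1 * nIter)
    stop("protocol failure: ", nAborted, " of ", nIter,
         " iterations aborted")
  new("TREResult", pairKind = pairKind, sectionLevel = sectionLevel,
      patientId = patientId, distances = unlist(distances),
      iterationOf = as.integer(unlist(iterOf)),
      perIterationMedian = perIterMedian[!is.na(perIterMedian)],
      nIterations = as.integer(nIter - nAborted),
      splitFraction = fraction, seed = as.integer(seed),
      nAborted = nAborted)
}

#' Summarize target registration errors
#'
#' Median, interquartile range (Q3 - Q1, linear-interpolation type-7
#' quantiles), mean and SD of the pooled distances, in mm.
#'
#' @param x A \linkS4class{TREResult} or a numeric vector of distances.
#' @return One-row data.frame with columns \code{median_mm}, \code{iqr_mm},
#'   \code{mean_mm}, \code{sd_mm}, \code{n}.
#' @examples
#' summarizeTRE(c(1, 2, 3, 4, 5))  # median 3, IQR 2
#' @export
summarizeTRE <- function(x) {
  d <- if (is(x, "TREResult")) x@distances else as.numeric(x)
  if (length(d) == 0L) stop("no distances to summarize")
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(median_mm = q[2], iqr_mm = q[3] - q[1], mean_mm = mean(d),
             sd_mm = if (length(d) > 1L) stats::sd(d) else 0,
             n = length(d))
}

#' Target registration error per tumor volume
#'
#' The ratio of a mean TRE (mm) to the tumor volume (mL), rounded to 3
#' decimals for reporting — a scale-free accuracy figure comparable across
#' specimens of very different size.
#'
#' @param meanTreMm Mean TRE in mm (>= 0).
#' @param volumeMl Tumor volume in mL (> 0).
#' @return TRE per volume in mm/mL, rounded to 3 decimals.
#' @examples
#' trePerVolume(2.145, 165.0)  # 0.013
#' @export
trePerVolume <- function(meanTreMm, volumeMl) {
  if (any(volumeMl <= 0)) stop("volume must be positive (mL)")
  if (any(meanTreMm < 0)) stop("TRE must be non-negative (mm)")
  round(meanTreMm / volumeMl, 3)
}

#' Nonparametric comparison of TRE groups
#'
#' Kruskal-Wallis test across all groups, then all pairwise Wilcoxon
#' rank-sum tests with Bonferroni correction (raw p multiplied by the
#' number of comparisons, capped at 1), flagged at the 0.05 level.
#'
#' @param groups Named list of numeric distance vectors or
#'   \linkS4class{TREResult}s (>= 2 groups, each non-empty).
#' @param alpha Significance level for the flags (default 0.05).
#' @return A list with \code{kruskal} (\code{H}, \code{df}, \code{p}),
#'   \code{pairwise} (data.frame with raw and Bonferroni-adjusted p), and
#'   \code{nComparisons}.
#' @export
compareTREGroups <- function(groups, alpha = 0.05) {
  vals <- lapply(groups, function(g)
    if (is(g, "TREResult")) g@distances else as.numeric(g))
  if (length(vals) < 2L) stop("need at least 2 groups")
  if (any(vapply(vals, length, 1L) == 0L)) stop("empty group")
  if (is.null(names(vals)))
    names(vals) <- paste0("group", seq_along(vals))
  kw <- stats::kruskal.test(vals)
  cmb <- utils::combn(names(vals), 2)
  m <- ncol(cmb)
  pw <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                   p_raw = NA_real_, p_bonferroni = NA_real_,
                   significant = NA, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    wt <- suppressWarnings(
      stats::wilcox.test(vals[[cmb[1, i]]], vals[[cmb[2, i]]]))
    pw$p_raw[i] <- wt$p.value
  }
  pw$p_bonferroni <- pmin(1, pw$p_raw * m)
  pw$significant <- pw$p_bonferroni < alpha
  list(kruskal = list(H = unname(kw$statistic), df = unname(kw$parameter),
                      p = kw$p.value),
       pairwise = pw, nComparisons = m)
}

#' Write pooled TRE distances as TSV
#'
#' One row per pooled distance with its metadata and iteration index.
#'
#' @param result A \linkS4class{TREResult}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeTREDistances <- function(result, path) {
  stopifnot(is(result, "TREResult"))
  df <- data.frame(pair_kind = result@pairKind,
                   section_level = result@sectionLevel,
                   patient_id = result@patientId,
                   iteration = result@iterationOf,
                   tre_mm = result@distances)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Box/jitter plot of TRE groups
#'
#' Boxplots of pooled TRE distances with jittered points overlaid, one box
#' per group.
#'
#' @param groups Named list of numeric vectors or \linkS4class{TREResult}s.
#' @param ylab Y-axis label.
#' @param ... Passed to \code{boxplot}.
#' @return Invisibly, the list of plotted values.
#' @export
plotTREGroups <- function(groups, ylab = "TRE (mm)", ...) {
  vals <- lapply(groups, function(g)
    if (is(g, "TREResult")) g@distances else as.numeric(g))
  graphics::boxplot(vals, outline = FALSE, ylab = ylab,
                    ylim = c(0, max(unlist(vals))), ...)
  for (i in seq_along(vals))
    graphics::points(jitter(rep(i, length(vals[[i]])), amount = 0.25),
                     vals[[i]], pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor(i + 1, 0.5))
  invisible(vals)
}
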