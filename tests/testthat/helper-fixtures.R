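# Shared fixture builders; everything is generated in code under fixed seeds.

randomLandmarks3D <- function(n = 40, seed = 1, extent = 60) {
  withr::with_seed(seed,
    LandmarkSet(matrix(runif(3 * n, 0, extent), n, 3), spaceName = "in_vivo"))
}

gridControls2D <- function(extentMm = c(30, 30), nPerSide = 4) {
  as.matrix(expand.grid(x = seq(0, extentMm[1], length.out = nPerSide),
                        y = seq(0, extentMm[2], length.out = nPerSide)))
}

# independent rotation-matrix construction via unit quaternion, used as an
# oracle against the package's axis-angle code
quaternionRotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  w <- cos(angle / 2); x <- sin(angle / 2) * a[1]
  y <- sin(angle / 2) * a[2]; z <- sin(angle / 2) * a[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# a TPS function with known controls/weights, evaluated by straightforward
# double-loop kernel summation (independent of the package's vectorized path)
bruteForceTPS <- function(ctrl, weights, affine, pts) {
  out <- matrix(0, nrow(pts), 2)
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    acc <- c(sum(c(1, p) * affine[, 1]), sum(c(1, p) * affine[, 2]))
    for (j in seq_len(nrow(ctrl))) {
      r <- sqrt(sum((p - ctrl[j, ])^2))
      u <- if (r > 0) r^2 * log(r) else 0
      acc <- acc + u * weights[j, ]
    }
    out[i, ] <- acc
  }
  out
}

# random TPS coefficients satisfying the side conditions exactly
randomTPSTruth <- function(ctrl, seed = 1, weightSd = 0.05) {
  withr::with_seed(seed, {
    W0 <- matrix(rnorm(2 * nrow(ctrl), 0, weightSd), ncol = 2)
    P <- cbind(1, ctrl)
    W <- W0 - P %*% solve(crossprod(P), crossprod(P, W0))
    A <- rbind(rnorm(2, 0, 2), diag(2) + matrix(rnorm(4, 0, 0.05), 2, 2))
    list(ctrl = ctrl, weights = W, affine = A)
  })
}
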