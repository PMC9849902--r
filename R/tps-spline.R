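.tpsU <- function(r2) {
  # radial basis r^2 log r = r2 * log(r2) / 2, with U(0) = 0
  out <- ifelse(r2 > 0, r2 * log(r2) / 2, 0)
  out
}

.pairwiseR2 <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}

.tpsL <- function(pts) {
  p <- nrow(pts)
  r2 <- .pairwiseR2(pts, pts)
  r2[r2 < 0] <- 0
  K <- .tpsU(r2)
  P <- cbind(1, pts)
  rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
}

#' Thin-plate-spline bending-energy kernel of a reference shape
#'
#' Builds the standard 2-D TPS bending-energy quadratic form (from the
#' radial basis r^2 log r): the p x p matrix B such that the bending energy
#' of a per-point displacement field d is
#' \code{t(d[,1]) B d[,1] + t(d[,2]) B d[,2]}. B is symmetric positive
#' semi-definite and vanishes exactly on affine displacement fields.
#'
#' @param reference numeric matrix p x 2, no duplicate points.
#' @return a [BendingKernel-class].
#' @export
bendingEnergyKernel <- function(reference) {
  reference <- as.matrix(reference)
  p <- nrow(reference)
  if (anyDuplicated(round(reference, 12)))
    stop("duplicate points make the TPS kernel singular")
  L <- .tpsL(reference)
  Linv <- solve(L)
  B <- Linv[seq_len(p), seq_len(p)]
  B <- (B + t(B)) / 2
  new("BendingKernel", reference = reference, energyMatrix = B)
}

#' Bending energy of a displacement field
#'
#' @param kernel a [BendingKernel-class].
#' @param displacement numeric matrix p x 2 (displacements per point), or a
#'   target shape minus the kernel's reference.
#' @return non-negative numeric.
#' @export
bendingEnergy <- function(kernel, displacement) {
  B <- kernel@energyMatrix
  as.numeric(t(displacement[, 1]) %*% B %*% displacement[, 1] +
             t(displacement[, 2]) %*% B %*% displacement[, 2])
}

# tangent unit vectors at the semi-landmarks of one specimen; NA rows where
# the tangent is undefined (coincident neighbors)
.curveTangents <- function(shape, scheme) {
  p <- nrow(shape)
  tang <- matrix(NA_real_, p, 2)
  for (cv in semiCurves(scheme)) {
    k <- length(cv)
    for (j in 2:(k - 1)) {
      v <- shape[cv[j + 1], ] - shape[cv[j - 1], ]
      nv <- sqrt(sum(v^2))
      if (nv > 1e-12) tang[cv[j], ] <- v / nv
    }
  }
  tang
}

# slide the semi-landmarks of every specimen in an n x p x 2 array
.slideArray <- function(X, scheme, kernel) {
  n <- dim(X)[1]
  cons <- kernel@reference
  B <- kernel@energyMatrix
  semis <- semiIndices(scheme)
  for (i in seq_len(n)) {
    sh <- X[i, , ]
    tang <- .curveTangents(sh, scheme)
    ok <- semis[is.finite(tang[semis, 1])]
    if (length(ok) < length(semis))
      warning("tangent undefined for ", length(semis) - length(ok),
              " semi-landmark(s); held fixed")
    if (length(ok) == 0) next
    d <- sh - cons
    Tm <- tang[ok, , drop = FALSE]
    Bss <- B[ok, ok, drop = FALSE]
    # joint minimization of the bending energy over the sliding amounts:
    # E(a) = sum_c (d_c + T_c a)' B (d_c + T_c a), T_c diagonal in t_{j,c}
    M <- Bss * (Tm %*% t(Tm))
    Bd <- B %*% d
    rhs <- -(Tm[, 1] * Bd[ok, 1] + Tm[, 2] * Bd[ok, 2])
    # tiny ridge keeps the solve well-posed; the regularized minimizer can
    # only decrease the energy relative to a = 0
    ridge <- 1e-10 * max(diag(M), 1e-12)
    a <- tryCatch(solve(M + diag(ridge, nrow(M)), rhs),
                  error = function(e) rep(0, length(ok)))
    sh[ok, ] <- sh[ok, ] + a * Tm
    X[i, , ] <- sh
  }
  X
}

#' Slide semi-landmarks by the minimum bending-energy criterion
#'
#' Moves each specimen's semi-landmarks along their local curve tangents
#' (central differences of the curve neighbors; anchors do not slide) so as
#' to minimize the thin-plate-spline bending energy of the specimen's
#' displacement from the kernel's reference (normally the consensus). The
#' sliding amounts of all semi-landmarks of a specimen are solved jointly
#' in closed form (one small linear system), so the per-specimen bending
#' energy never increases. Fixed landmarks and curve anchor endpoints are
#' never moved; a semi-landmark whose tangent is undefined (coincident
#' neighbors) is held fixed with a warning.
#'
#' @param aligned an [AlignedShapeSet-class].
#' @param scheme [LandmarkScheme-class]; defaults to the set's scheme.
#' @param kernel a [BendingKernel-class] built on the current consensus;
#'   computed from `aligned@consensus` when absent.
#' @return an [AlignedShapeSet-class] with slid (re-centered, re-scaled)
#'   coordinates and updated consensus.
#' @export
slideSemilandmarks <- function(aligned, scheme = NULL, kernel = NULL) {
  stopifnot(is(aligned, "AlignedShapeSet"))
  if (is.null(scheme)) scheme <- landmarkScheme(aligned)
  if (is.null(kernel)) kernel <- bendingEnergyKernel(aligned@consensus)
  X <- .slideArray(shapeCoords(aligned), scheme, kernel)
  for (i in seq_len(dim(X)[1])) {
    sh <- .center(X[i, , ])
    X[i, , ] <- sh / sqrt(sum(sh^2))
  }
  initialize(aligned, coords = X, consensus = apply(X, c(2, 3), mean))
}

#' Thin-plate-spline warp
#'
#' The 2-D TPS interpolant mapping `source` landmarks exactly onto
#' `target` landmarks, evaluated at arbitrary points. Exactly reproduces
#' affine maps (zero bending energy).
#'
#' @param source,target numeric matrices p x 2 (equal p, no duplicate
#'   source points).
#' @param points numeric matrix m x 2 of evaluation points.
#' @return numeric matrix m x 2 of warped points.
#' @examples
#' src <- rbind(c(0,0), c(1,0), c(0,1), c(1,1))
#' tpsWarp(src, src * 2, rbind(c(0.5, 0.5)))  # c(1, 1)
#' @export
tpsWarp <- function(source, target, points) {
  source <- as.matrix(source); target <- as.matrix(target)
  points <- matrix(as.numeric(points), ncol = 2)
  stopifnot(nrow(source) == nrow(target))
  if (anyDuplicated(round(source, 12)))
    stop("duplicate source points make the TPS system singular")
  p <- nrow(source)
  L <- .tpsL(source)
  rhs <- rbind(target, matrix(0, 3, 2))
  coefs <- solve(L, rhs)           # (p+3) x 2: weights then affine part
  r2 <- .pairwiseR2(points, source)
  r2[r2 < 0] <- 0
  U <- .tpsU(r2)
  cbind(1, points) %*% coefs[p + (1:3), ] + U %*% coefs[seq_len(p), ]
}

#' Exaggerate a group mean away from the consensus
#'
#' Linear extrapolation `consensus + k * (groupMean - consensus)`; `k = 1`
#' is the group mean itself, `k = 3` a three-fold exaggeration used to make
#' subtle dimorphic shape differences visible.
#'
#' @param consensus,groupMean numeric matrices p x 2.
#' @param k exaggeration factor.
#' @return numeric matrix p x 2.
#' @export
exaggerateShape <- function(consensus, groupMean, k) {
  stopifnot(all(dim(consensus) == dim(groupMean)))
  consensus + k * (groupMean - consensus)
}

#' Thin-plate-spline deformation grid
#'
#' A rectangular grid spanning the consensus bounding box (plus a margin),
#' warped by the TPS map taking the consensus onto the target shape.
#' Undistorted when `target == consensus`; uniformly scaled for a uniformly
#' scaled target (affine exactness).
#'
#' @param consensus,target numeric matrices p x 2 (aligned shapes).
#' @param gridDensity integer length-2, number of grid lines (columns,
#'   rows); default c(24, 24).
#' @param margin fractional bounding-box margin (default 0.05).
#' @param pointsPerLine sampling density along each grid line.
#' @return data.frame with columns `line` (id), `dir` ("h"/"v"), `x`, `y`:
#'   warped polylines ready for plotting.
#' @export
deformationGrid <- function(consensus, target, gridDensity = c(24, 24),
                            margin = 0.05, pointsPerLine = 50) {
  rngx <- range(consensus[, 1]); rngy <- range(consensus[, 2])
  mx <- margin * diff(rngx); my <- margin * diff(rngy)
  xs <- seq(rngx[1] - mx, rngx[2] + mx, length.out = gridDensity[1])
  ys <- seq(rngy[1] - my, rngy[2] + my, length.out = gridDensity[2])
  xfine <- seq(min(xs), max(xs), length.out = pointsPerLine)
  yfine <- seq(min(ys), max(ys), length.out = pointsPerLine)
  nodes <- rbind(
    do.call(rbind, lapply(seq_along(ys), function(i)
      cbind(line = i, dir = 1, x = xfine, y = ys[i]))),
    do.call(rbind, lapply(seq_along(xs), function(i)
      cbind(line = i, dir = 2, x = xs[i], y = yfine))))
  warped <- tpsWarp(consensus, target, nodes[, c("x", "y")])
  data.frame(line = nodes[, "line"],
             dir = c("h", "v")[nodes[, "dir"]],
             x = warped[, 1], y = warped[, 2])
}

#' Plot a deformation grid with an overlaid shape
#'
#' @param grid a data.frame from [deformationGrid()].
#' @param shape optional p x 2 matrix overlaid as points.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotDeformationGrid <- function(grid, shape = NULL, ...) {
  graphics::plot(grid$x, grid$y, type = "n", asp = 1, xlab = "", ylab = "",
                 axes = FALSE, ...)
  for (d in c("h", "v")) for (l in unique(grid$line[grid$dir == d])) {
    seg <- grid[grid$dir == d & grid$line == l, ]
    graphics::lines(seg$x, seg$y, col = "grey60")
  }
  if (!is.null(shape)) graphics::points(shape, pch = 19, cex = 0.5)
  invisible(NULL)
}
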