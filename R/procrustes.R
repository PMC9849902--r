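#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the points to their
#' centroid: the size measure removed by Procrustes superimposition.
#'
#' @param shape numeric matrix p x 2.
#' @return positive numeric.
#' @export
centroidSize <- function(shape) {
  cen <- colMeans(shape)
  sqrt(sum(sweep(shape, 2, cen)^2))
}

.center <- function(shape) sweep(shape, 2, colMeans(shape))

# optimal rotation angle of centered X onto centered Y (proper, det +1)
.rotAngle <- function(X, Y) {
  a <- sum(X * Y)
  b <- sum(X[, 2] * Y[, 1] - X[, 1] * Y[, 2])
  atan2(b, a)
}

.rotMat <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Least-squares similarity superimposition of one shape onto another
#'
#' Finds the proper rotation (determinant +1; reflections are never used,
#' so faces cannot mirror during alignment), scale and translation
#' minimizing the summed squared distances between the transformed moving
#' configuration and the target.
#'
#' @param moving,target numeric matrices p x 2 (equal p >= 3).
#' @return list with `rotation` (2 x 2 matrix), `scale`, `translation`
#'   (length-2: applied after rotation/scaling of the centered shape),
#'   `aligned` (p x 2), and `residual` (root summed squared distance).
#' @examples
#' sq <- rbind(c(0,0), c(1,0), c(1,1), c(0,1))
#' fit <- optimalSuperimposition(sq * 2, sq)
#' fit$scale  # 0.5
#' @export
optimalSuperimposition <- function(moving, target) {
  stopifnot(nrow(moving) == nrow(target), nrow(moving) >= 3)
  Xc <- .center(moving); Yc <- .center(target)
  sx <- sqrt(sum(Xc^2))
  if (sx < 1e-12 || sqrt(sum(Yc^2)) < 1e-12)
    stop("degenerate shape: all points coincident")
  theta <- .rotAngle(Xc, Yc)
  R <- .rotMat(theta)
  XR <- Xc %*% R
  s <- sum(XR * Yc) / sum(Xc^2)
  translation <- colMeans(target)
  aligned <- sweep(s * XR, 2, translation, "+")
  list(rotation = R, scale = s, translation = translation,
       aligned = aligned, residual = sqrt(sum((aligned - target)^2)))
}

#' Procrustes distance between two aligned shapes
#'
#' Root summed squared point-wise difference after optimally rotating the
#' second shape onto the first. Both shapes must already be centered with
#' unit centroid size (as produced by [gpa()]); the measure is symmetric.
#'
#' @param a,b numeric matrices p x 2, centered, unit centroid size.
#' @param tol tolerance for the centering/size preconditions.
#' @return non-negative numeric.
#' @export
procrustesDistance <- function(a, b, tol = 1e-6) {
  if (!all(dim(a) == dim(b))) stop("shape dimensions differ")
  if (max(abs(colMeans(a)), abs(colMeans(b))) > tol ||
      abs(sqrt(sum(a^2)) - 1) > tol || abs(sqrt(sum(b^2)) - 1) > tol)
    stop("shapes must be centered with unit centroid size")
  R <- .rotMat(.rotAngle(b, a))
  sqrt(sum((b %*% R - a)^2))
}

#' Generalized Procrustes superimposition with optional sliding
#'
#' Standardizes a set of configurations for position, orientation and
#' scale: each shape is centered and scaled to unit centroid size, then
#' iteratively rotated onto the current consensus (the arithmetic mean of
#' the aligned shapes), which is updated until its root-mean-square change
#' falls below `tol`. When `slide = TRUE`, semi-landmarks are slid along
#' their curve tangents under the minimum thin-plate-spline bending-energy
#' criterion once per iteration (kernel rebuilt on the updated consensus;
#' see [slideSemilandmarks()]), after which shapes are re-centered and
#' rescaled. Rotations are always proper, so configurations never reflect.
#'
#' @param shapes a [ShapeSet-class], or an n x p x 2 array.
#' @param scheme [LandmarkScheme-class]; taken from `shapes` when absent.
#'   Required only for sliding.
#' @param slide slide semi-landmarks (default FALSE).
#' @param tol convergence tolerance on the RMS consensus change
#'   (default 1e-8).
#' @param maxIter iteration cap (default 100); on hitting it the result is
#'   returned flagged `converged = FALSE`, no error is thrown.
#' @param slideIters number of initial iterations in which sliding is
#'   interleaved (default 5). Because a fresh full bending-energy
#'   relaxation against an updated consensus re-excites a small tangential
#'   smoothing drift on noisy data, sliding is applied during the first
#'   `slideIters` iterations (by which point per-pass movements are far
#'   below digitization noise) and the semi-landmark positions are then
#'   frozen so the superimposition itself converges tightly.
#' @return an [AlignedShapeSet-class].
#' @examples
#' sq <- rbind(c(0,0), c(1,0), c(1,1), c(0,1))
#' ss <- ShapeSet(list(sq, sq * 3 + 1))
#' gpa(ss)@consensus
#' @export
gpa <- function(shapes, scheme = NULL, slide = FALSE, tol = 1e-8,
                maxIter = 100L, slideIters = 5L) {
  if (is(shapes, "ShapeSet")) {
    if (is.null(scheme)) scheme <- landmarkScheme(shapes)
    info <- sampleInfo(shapes)
    co <- shapeCoords(shapes)
  } else {
    co <- shapes
    info <- NULL
  }
  n <- dim(co)[1]; p <- dim(co)[2]
  stopifnot(n >= 2)
  if (slide && (is.null(scheme) || length(semiCurves(scheme)) == 0))
    stop("sliding requires a scheme with semi-landmark curves")
  sizes <- numeric(n)
  X <- array(NA_real_, dim(co))
  for (i in seq_len(n)) {
    sh <- .center(co[i, , ])
    sizes[i] <- sqrt(sum(sh^2))
    if (sizes[i] < 1e-12) stop("degenerate shape at sample ", i)
    X[i, , ] <- sh / sizes[i]
  }
  # initial consensus: first shape; all rotations relative to it
  consensus <- X[1, , ]
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    for (i in seq_len(n)) {
      R <- .rotMat(.rotAngle(X[i, , ], consensus))
      X[i, , ] <- X[i, , ] %*% R
    }
    if (slide && it <= slideIters) {
      cons <- apply(X, c(2, 3), mean)
      kernel <- bendingEnergyKernel(cons)
      X <- .slideArray(X, scheme, kernel)
      for (i in seq_len(n)) {
        sh <- .center(X[i, , ])
        X[i, , ] <- sh / sqrt(sum(sh^2))
      }
    }
    newCons <- apply(X, c(2, 3), mean)
    newCons <- newCons / sqrt(sum(.center(newCons)^2))
    delta <- sqrt(mean((newCons - consensus)^2))
    consensus <- newCons
    if (delta < tol) { converged <- TRUE; break }
    if (it >= maxIter) break
  }
  cons <- apply(X, c(2, 3), mean)
  if (is.null(info)) {
    base <- ShapeSet(X, scheme = scheme)
    info <- sampleInfo(base)
  }
  new("AlignedShapeSet", coords = X, info = info,
      scheme = if (is.null(scheme)) LandmarkScheme(p, seq_len(p)) else scheme,
      centroidSizes = sizes, consensus = cons,
      nIterations = it, converged = converged)
}
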