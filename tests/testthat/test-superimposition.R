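test_that("optimal superimposition recovers constructed transforms", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.2, 0.8))
  fit0 <- optimalSuperimposition(sq, sq)
  expect_lt(fit0$residual, 1e-12)
  expect_equal(fit0$scale, 1, tolerance = 1e-12)
  # moving = target rotated 90 degrees and scaled x2
  R90 <- matrix(c(0, 1, -1, 0), 2, 2)
  moving <- 2 * sq %*% R90
  fit <- optimalSuperimposition(moving, sq)
  expect_equal(fit$scale, 0.5, tolerance = 1e-12)
  expect_lt(fit$residual, 1e-12)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  expect_error(optimalSuperimposition(matrix(1, 5, 2), sq), "degenerate")
})

test_that("superimposition residual matches a brute-force grid search", {
  set.seed(11)
  X <- matrix(rnorm(10), 5, 2)
  Y <- matrix(rnorm(10), 5, 2)
  fit <- optimalSuperimposition(X, Y)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  grid <- expand.grid(theta = seq(0, 2 * pi, length.out = 4000),
                      s = seq(0.05, 3, length.out = 200))
  best <- min(vapply(seq_len(nrow(grid)), function(i) {
    th <- grid$theta[i]
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    sum((grid$s[i] * Xc %*% R - Yc)^2)
  }, 0))
  expect_lt(fit$residual^2, best + 1e-10)
  expect_equal(fit$residual^2, best, tolerance = 1e-3)
})

test_that("GPA aligns identical and similarity-transformed copies exactly", {
  base <- randomShapes(1, p = 8, seed = 5)[[1]]
  idn <- gpa(ShapeSet(list(base, base, base)))
  expect_equal(idn@nIterations, 1L)
  expect_true(idn@converged)
  co <- shapeCoords(idn)
  expect_lt(max(abs(co[1, , ] - co[2, , ])), 1e-12)
  expect_equal(consensusShape(idn), co[1, , ], tolerance = 1e-12)
  # arbitrary similarity transforms of one shape
  set.seed(8)
  copies <- lapply(1:6, function(i) {
    th <- runif(1, -pi, pi)
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    runif(1, 0.2, 4) * base %*% R + matrix(runif(2, -5, 5), 8, 2,
                                           byrow = TRUE)
  })
  al <- gpa(ShapeSet(copies))
  co <- shapeCoords(al)
  for (i in 2:6)
    expect_lt(procrustesDistance(co[1, , ], co[i, , ]), 1e-8)
})

test_that("two-shape GPA matches the closed-form orthogonal solution", {
  sh <- randomShapes(2, p = 6, noise = 0.2, seed = 21)
  al <- gpa(ShapeSet(sh), tol = 1e-12)
  co <- shapeCoords(al)
  norm1 <- function(x) { x <- sweep(x, 2, colMeans(x)); x / sqrt(sum(x^2)) }
  fit <- optimalSuperimposition(norm1(sh[[2]]), norm1(sh[[1]]))
  # residual distance between the two aligned shapes equals the direct
  # orthogonal Procrustes residual of the unit-size shapes
  d <- procrustesDistance(co[1, , ], co[2, , ])
  direct <- sqrt(sum((norm1(sh[[2]]) %*% fit$rotation
                      - norm1(sh[[1]]))^2))
  expect_equal(d, direct, tolerance = 1e-6)
  # consensus is the midpoint of the two aligned shapes
  expect_equal(consensusShape(al), (co[1, , ] + co[2, , ]) / 2,
               tolerance = 1e-10)
})

test_that("Procrustes distance to the consensus is non-increasing over GPA iterations", {
  faces <- generateFaces(faceSimConfig(nMale = 6, nFemale = 6, seed = 4))
  ssq <- vapply(1:6, function(k) {
    al <- gpa(faces, maxIter = k, tol = 0)
    co <- shapeCoords(al)
    cons <- consensusShape(al)
    sum(vapply(seq_len(dim(co)[1]), function(i)
      sum((co[i, , ] - cons)^2), 0))
  }, 0)
  expect_true(all(diff(ssq) <= 1e-10))
})

test_that("Procrustes distance is symmetric and matches a 1-D optimization oracle", {
  sh <- randomShapes(2, p = 6, noise = 0.3, seed = 13)
  norm1 <- function(x) { x <- sweep(x, 2, colMeans(x)); x / sqrt(sum(x^2)) }
  a <- norm1(sh[[1]]); b <- norm1(sh[[2]])
  expect_equal(procrustesDistance(a, a), 0, tolerance = 1e-12)
  expect_equal(procrustesDistance(a, b), procrustesDistance(b, a),
               tolerance = 1e-12)
  oracle <- stats::optimize(function(th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    sqrt(sum((b %*% t(R) - a)^2))
  }, c(-pi, pi), tol = 1e-12)$objective
  expect_equal(procrustesDistance(a, b), oracle, tolerance = 1e-8)
  expect_error(procrustesDistance(a, b * 2), "unit centroid")
})

test_that("bending energy vanishes on affine fields and matches an independent kernel", {
  ref <- faceTemplate()
  k <- bendingEnergyKernel(ref)
  # pure translation and pure shear/affine fields have zero energy
  transl <- matrix(c(0.3, -0.2), nrow(ref), 2, byrow = TRUE)
  affine <- cbind(0.2 * ref[, 1] - 0.7 * ref[, 2],
                  0.4 * ref[, 1] + 0.1 * ref[, 2])
  expect_lt(abs(bendingEnergy(k, transl)), 1e-8)
  expect_lt(abs(bendingEnergy(k, affine)), 1e-8)
  # PSD
  expect_gt(min(eigen(k@energyMatrix, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-8)
  # single interior point displaced on a 3x3 grid: quadratic form agrees
  # with an independently coded kernel inversion
  grid <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  kg <- bendingEnergyKernel(grid)
  Bo <- oracleBendingMatrix(grid)
  d <- matrix(0, 9, 2); d[5, 2] <- 0.3
  expect_equal(bendingEnergy(kg, d),
               as.numeric(t(d[, 2]) %*% Bo %*% d[, 2]),
               tolerance = 1e-10)
  expect_error(bendingEnergyKernel(rbind(grid, c(0, 0))), "duplicate")
})

test_that("sliding restores a tangential perturbation and never moves fixed landmarks", {
  scheme <- defaultLandmarkScheme()
  tpl <- faceTemplate()
  ref <- sweep(tpl, 2, colMeans(tpl)); ref <- ref / sqrt(sum(ref^2))
  kernel <- bendingEnergyKernel(ref)
  j <- semiCurves(scheme)$outline[10]          # an interior outline point
  nb <- semiCurves(scheme)$outline[c(9, 11)]
  tang <- ref[nb[2], ] - ref[nb[1], ]
  tang <- tang / sqrt(sum(tang^2))
  pert <- ref
  pert[j, ] <- pert[j, ] + 5e-3 * tang
  X <- array(NA_real_, c(2, nrow(ref), 2))
  X[1, , ] <- ref; X[2, , ] <- pert
  slid <- FaceTrust:::.slideArray(X, scheme, kernel)
  # a specimen equal to the reference does not move at all
  expect_equal(slid[1, , ], ref, tolerance = 1e-12, ignore_attr = TRUE)
  # fixed landmarks of the perturbed specimen are untouched
  expect_equal(slid[2, fixedIndices(scheme), ],
               pert[fixedIndices(scheme), ], tolerance = 1e-12,
               ignore_attr = TRUE)
  # the perturbation is slid back: Procrustes residual far below the
  # perturbation size, and the bending energy strictly decreases
  e0 <- bendingEnergy(kernel, pert - ref)
  e1 <- bendingEnergy(kernel, slid[2, , ] - ref)
  expect_lt(e1, e0)
  expect_lt(optimalSuperimposition(slid[2, , ], ref)$residual, 1e-6)
})

test_that("sliding never increases the bending energy of noisy specimens", {
  faces <- generateFaces(faceSimConfig(nMale = 5, nFemale = 5, seed = 9))
  al <- gpa(faces, slide = FALSE)
  kernel <- bendingEnergyKernel(consensusShape(al))
  co <- shapeCoords(al)
  slid <- FaceTrust:::.slideArray(co, landmarkScheme(al), kernel)
  for (i in seq_len(dim(co)[1])) {
    e0 <- bendingEnergy(kernel, co[i, , ] - kernel@reference)
    e1 <- bendingEnergy(kernel, slid[i, , ] - kernel@reference)
    expect_lte(e1, e0 + 1e-12)
  }
  # and through the public interface the invariants still hold
  slid2 <- slideSemilandmarks(al)
  expect_true(validObject(slid2))
})

test_that("TPS warps interpolate exactly and reproduce affine maps", {
  src <- randomShapes(1, p = 8, seed = 31)[[1]]
  pts <- matrix(runif(20, -1, 1), 10, 2)
  # target = source: identity everywhere
  expect_equal(tpsWarp(src, src, pts), pts, tolerance = 1e-8)
  # evaluated at the source landmarks: exactly the target landmarks
  set.seed(32)
  tgt <- src + matrix(rnorm(16, sd = 0.1), 8, 2)
  expect_equal(tpsWarp(src, tgt, src), tgt, tolerance = 1e-8)
  # affine target: warp agrees with the affine map everywhere
  A <- matrix(c(1.2, 0.3, -0.2, 0.8), 2, 2); b <- c(0.5, -1)
  affTgt <- sweep(src %*% t(A), 2, b, "+")
  expect_equal(tpsWarp(src, affTgt, pts),
               sweep(pts %*% t(A), 2, b, "+"), tolerance = 1e-8)
  expect_error(tpsWarp(rbind(src, src[1, ]), rbind(tgt, tgt[1, ]), pts),
               "duplicate")
})

test_that("shape exaggeration is the stated linear extrapolation", {
  cons <- randomShapes(1, seed = 41)[[1]]
  gm <- cons + 0.1
  expect_equal(exaggerateShape(cons, gm, 0), cons)
  expect_equal(exaggerateShape(cons, gm, 1), gm)
  expect_equal(exaggerateShape(cons, gm, 3) - cons,
               3 * (exaggerateShape(cons, gm, 1) - cons))
})

test_that("deformation grids are consistent with the TPS warp", {
  cons <- faceTemplate()
  # identity target: grid nodes are the unwarped lattice
  g0 <- deformationGrid(cons, cons, gridDensity = c(6, 6),
                        pointsPerLine = 8)
  horiz <- g0[g0$dir == "h" & g0$line == 3, ]
  expect_equal(length(unique(round(horiz$y, 9))), 1L)
  # uniformly scaled target: uniformly scaled grid
  g2 <- deformationGrid(cons, cons * 2, gridDensity = c(6, 6),
                        pointsPerLine = 8)
  expect_equal(g2$x, g0$x * 2, tolerance = 1e-8)
  expect_equal(g2$y, g0$y * 2, tolerance = 1e-8)
  # node positions equal tpsWarp evaluated at those nodes (definitional)
  set.seed(51)
  tgt <- cons + matrix(rnorm(length(cons), sd = 0.02), nrow(cons), 2)
  g <- deformationGrid(cons, tgt, gridDensity = c(5, 5), pointsPerLine = 6)
  nodes0 <- deformationGrid(cons, cons, gridDensity = c(5, 5),
                            pointsPerLine = 6)
  direct <- tpsWarp(cons, tgt, as.matrix(nodes0[, c("x", "y")]))
  expect_equal(as.matrix(g[, c("x", "y")]), direct, tolerance = 1e-8,
               ignore_attr = TRUE)
})
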