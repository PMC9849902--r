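#' @import methods
NULL

#' LandmarkScheme: topology of a landmark configuration
#'
#' Describes which points of a configuration are fixed anatomical landmarks
#' and which are sliding semi-landmarks, together with the curve topology of
#' the semi-landmarks. Each curve is an ordered index vector whose first and
#' last entries are non-sliding anchors (fixed landmarks); the interior
#' points are the semi-landmarks that slide along the curve.
#'
#' @slot nTotal integer, number of points per configuration.
#' @slot fixedIndices integer vector of fixed-landmark indices (1-based).
#' @slot semiCurves list of integer vectors, one per curve, ordered along
#'   the curve, anchors at both ends.
#' @slot curveNames character vector naming the curves.
#' @export
setClass("LandmarkScheme",
  representation(nTotal = "integer", fixedIndices = "integer",
                 semiCurves = "list", curveNames = "character"))

setValidity("LandmarkScheme", function(object) {
  msg <- NULL
  n <- object@nTotal
  semis <- semiIndices(object)
  if (length(object@semiCurves) > 0 &&
      any(vapply(object@semiCurves, length, 1L) < 3))
    msg <- c(msg, "each curve must have at least 3 points")
  if (!setequal(c(object@fixedIndices, semis), seq_len(n)) ||
      length(intersect(object@fixedIndices, semis)) > 0)
    msg <- c(msg, "fixed and semi-landmark indices must partition 1..nTotal")
  anchors <- unlist(lapply(object@semiCurves, function(cv)
    cv[c(1L, length(cv))]))
  if (!all(anchors %in% object@fixedIndices))
    msg <- c(msg, "curve anchor endpoints must be fixed landmarks")
  if (is.null(msg)) TRUE else msg
})

#' ShapeSet: a set of 2-D landmark configurations with metadata
#'
#' @slot coords numeric array n_samples x n_points x 2.
#' @slot info data.frame with one row per sample; columns
#'   \code{individual_id}, \code{sex}, \code{age}, \code{origin},
#'   \code{observer_id}, \code{beard}, \code{head_deviation}.
#' @slot scheme a [LandmarkScheme-class].
#' @export
setClass("ShapeSet",
  representation(coords = "array", info = "data.frame",
                 scheme = "LandmarkScheme"))

setValidity("ShapeSet", function(object) {
  msg <- NULL
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 2)
    msg <- c(msg, "coords must be an n x p x 2 array")
  else {
    if (d[2] != object@scheme@nTotal)
      msg <- c(msg, "point count does not match scheme nTotal")
    if (d[1] != nrow(object@info))
      msg <- c(msg, "info rows must match number of samples")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coords contain non-finite values")
  }
  need <- c("individual_id", "sex", "age", "origin", "observer_id",
            "beard", "head_deviation")
  miss <- setdiff(need, names(object@info))
  if (length(miss) > 0)
    msg <- c(msg, paste("info lacks columns:", paste(miss, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' AlignedShapeSet: Procrustes-superimposed configurations
#'
#' A [ShapeSet-class] after Generalized Procrustes superimposition: every
#' configuration is centered at the origin with unit centroid size, and the
#' consensus is the arithmetic mean of the aligned coordinates.
#'
#' @slot centroidSizes numeric, original centroid size per sample.
#' @slot consensus numeric matrix n_points x 2, mean aligned shape.
#' @slot nIterations integer, superimposition iterations used.
#' @slot converged logical.
#' @export
setClass("AlignedShapeSet", contains = "ShapeSet",
  representation(centroidSizes = "numeric", consensus = "matrix",
                 nIterations = "integer", converged = "logical"))

setValidity("AlignedShapeSet", function(object) {
  msg <- NULL
  tol <- 1e-8
  n <- dim(object@coords)[1]
  if (length(object@centroidSizes) != n)
    msg <- c(msg, "centroidSizes length must match sample count")
  if (any(object@centroidSizes <= 0))
    msg <- c(msg, "centroid sizes must be positive")
  cents <- apply(object@coords, c(1, 3), mean)
  if (max(abs(cents)) > tol)
    msg <- c(msg, "aligned shapes must be centered at the origin")
  sizes <- sqrt(apply(object@coords^2, 1, sum))
  if (n > 0 && max(abs(sizes - 1)) > tol)
    msg <- c(msg, "aligned shapes must have unit centroid size")
  cons <- apply(object@coords, c(2, 3), mean)
  if (max(abs(cons - object@consensus)) > 1e-8)
    msg <- c(msg, "consensus must equal the mean of aligned coordinates")
  if (is.null(msg)) TRUE else msg
})

#' BendingKernel: thin-plate-spline bending-energy quadratic form
#'
#' @slot reference numeric matrix n_points x 2, the reference configuration.
#' @slot energyMatrix symmetric PSD matrix over per-point displacements; the
#'   bending energy of a displacement field d (n_points x 2) is
#'   \code{t(d[,1]) \%*\% B \%*\% d[,1] + t(d[,2]) \%*\% B \%*\% d[,2]}.
#' @export
setClass("BendingKernel",
  representation(reference = "matrix", energyMatrix = "matrix"))

setValidity("BendingKernel", function(object) {
  msg <- NULL
  if (nrow(object@reference) != nrow(object@energyMatrix))
    msg <- c(msg, "energy matrix dimension must match reference points")
  if (max(abs(object@energyMatrix - t(object@energyMatrix))) > 1e-8)
    msg <- c(msg, "energy matrix must be symmetric")
  if (is.null(msg)) TRUE else msg
})

#' FemininityScores: discriminant facial shape scores
#'
#' Per-individual scores along the two-group (female vs male) discriminant
#' axis of Procrustes shape space, oriented so that higher scores are more
#' feminine, plus within-sex z-standardizations in up to two contexts: the
#' full analysis sample (\code{z_full}) and a designated subsample such as
#' the stimulus partners (\code{z_partner}).
#'
#' @slot scores data.frame with columns \code{individual_id}, \code{sex},
#'   \code{raw_score}, \code{z_full}, \code{z_partner} (NA outside the
#'   subsample).
#' @slot axis numeric matrix n_points x 2, discriminant direction in
#'   coordinate space (unit norm), for visualization.
#' @export
setClass("FemininityScores",
  representation(scores = "data.frame", axis = "matrix"))

setValidity("FemininityScores", function(object) {
  msg <- NULL
  need <- c("individual_id", "sex", "raw_score", "z_full", "z_partner")
  miss <- setdiff(need, names(object@scores))
  if (length(miss) > 0)
    msg <- c(msg, paste("scores lacks columns:", paste(miss, collapse = ", ")))
  else {
    s <- object@scores
    for (g in unique(s$sex)) {
      z <- s$z_full[s$sex == g]
      if (length(z) >= 2 && all(is.finite(z))) {
        if (abs(mean(z)) > 1e-10 || abs(stats::sd(z) - 1) > 1e-10)
          msg <- c(msg, "within-sex z_full must have mean 0 and SD 1")
      }
    }
    mf <- mean(s$raw_score[s$sex == "female"])
    mm <- mean(s$raw_score[s$sex == "male"])
    if (is.finite(mf) && is.finite(mm) && mf <= mm)
      msg <- c(msg, "orientation: female mean raw score must exceed male mean")
  }
  if (is.null(msg)) TRUE else msg
})

#' PermutationTestResult: distance-based permutation MANOVA decomposition
#'
#' @slot factorNames character, predictors in entry (sequential) order.
#' @slot ss named numeric, sequential sums of squares plus "Residual".
#' @slot df named numeric, degrees of freedom per term.
#' @slot varianceExplained named numeric, per-factor fraction of total SS.
#' @slot pseudoF named numeric.
#' @slot pPerm named numeric, permutation p-values.
#' @slot nPermutations integer.
#' @slot seed integer seed used for the permutations (NA if enumerated).
#' @slot nSamples integer.
#' @slot flagged logical, TRUE when the test is undefined (e.g. zero total
#'   sum of squares).
#' @export
setClass("PermutationTestResult",
  representation(factorNames = "character", ss = "numeric", df = "numeric",
                 varianceExplained = "numeric", pseudoF = "numeric",
                 pPerm = "numeric", nPermutations = "integer",
                 seed = "integer", nSamples = "integer", flagged = "logical"))

#' KappaResult: Fleiss' kappa multi-rater agreement
#'
#' @slot kappa numeric.
#' @slot z numeric, large-sample normal statistic against kappa = 0.
#' @slot p numeric, two-sided p-value.
#' @slot nItems integer. @slot nRatings integer, ratings per item.
#' @slot categories character. @slot flagged logical (TRUE when undefined).
#' @export
setClass("KappaResult",
  representation(kappa = "numeric", z = "numeric", p = "numeric",
                 nItems = "integer", nRatings = "integer",
                 categories = "character", flagged = "logical"))

#' GEEResult: generalized estimating equations fit
#'
#' Marginal regression with repeated measures: coefficient estimates with
#' robust (sandwich) standard errors and per-coefficient Wald chi-squared
#' tests on 1 degree of freedom.
#'
#' @slot coefficients named numeric (B).
#' @slot robustSE named numeric.
#' @slot waldX2 named numeric, \code{(B / robustSE)^2}.
#' @slot p named numeric, from the chi-squared(1) distribution.
#' @slot family character, "binomial" (logit) or "gaussian" (identity).
#' @slot workingCorrelation character. @slot alpha numeric, estimated
#'   within-cluster working correlation.
#' @slot nClusters integer. @slot nObs integer.
#' @slot nIterations integer. @slot converged logical.
#' @export
setClass("GEEResult",
  representation(coefficients = "numeric", robustSE = "numeric",
                 waldX2 = "numeric", p = "numeric", family = "character",
                 workingCorrelation = "character", alpha = "numeric",
                 nClusters = "integer", nObs = "integer",
                 nIterations = "integer", converged = "logical"))

setValidity("GEEResult", function(object) {
  w <- (object@coefficients / object@robustSE)^2
  if (max(abs(w - object@waldX2)) > 1e-6)
    "waldX2 must equal (B / robust SE)^2" else TRUE
})

#' MAResult: model-II major-axis regression
#'
#' @slot slope numeric. @slot intercept numeric.
#' @slot rSquared numeric, squared Pearson correlation.
#' @slot p numeric, two-sided significance of the association.
#' @slot n integer.
#' @export
setClass("MAResult",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", p = "numeric", n = "integer"))

#' TestResult: a classical two-sample / contingency test
#'
#' @slot statisticName character, one of "X2", "Fisher-p", "U".
#' @slot statistic numeric. @slot df numeric (NA when not applicable).
#' @slot p numeric.
#' @export
setClass("TestResult",
  representation(statisticName = "character", statistic = "numeric",
                 df = "numeric", p = "numeric"))
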