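#' @include AllClasses.R
NULL

#' Accessors for landmark schemes and shape sets
#'
#' \code{semiIndices} returns the sorted indices of all sliding
#' semi-landmarks of a scheme; \code{fixedIndices} the fixed landmarks;
#' \code{semiCurves} the curve topology. \code{shapeCoords} returns the
#' n x p x 2 coordinate array of a [ShapeSet-class]; \code{sampleInfo} its
#' per-sample metadata; \code{landmarkScheme} its scheme.
#' \code{centroidSizes}, \code{consensusShape}, \code{isConverged} access
#' [AlignedShapeSet-class] slots, and \code{femininityTable} the score table
#' of a [FemininityScores-class].
#'
#' @param x the object.
#' @return the slot value (see above).
#' @name accessors
#' @aliases semiIndices fixedIndices semiCurves shapeCoords sampleInfo
#'   landmarkScheme centroidSizes consensusShape isConverged femininityTable
NULL

#' @rdname accessors
#' @export
setGeneric("semiIndices", function(x) standardGeneric("semiIndices"))
#' @rdname accessors
#' @export
setGeneric("fixedIndices", function(x) standardGeneric("fixedIndices"))
#' @rdname accessors
#' @export
setGeneric("semiCurves", function(x) standardGeneric("semiCurves"))
#' @rdname accessors
#' @export
setGeneric("shapeCoords", function(x) standardGeneric("shapeCoords"))
#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setGeneric("landmarkScheme", function(x) standardGeneric("landmarkScheme"))
#' @rdname accessors
#' @export
setGeneric("centroidSizes", function(x) standardGeneric("centroidSizes"))
#' @rdname accessors
#' @export
setGeneric("consensusShape", function(x) standardGeneric("consensusShape"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("femininityTable", function(x) standardGeneric("femininityTable"))

setMethod("semiIndices", "LandmarkScheme", function(x) {
  if (length(x@semiCurves) == 0) return(integer(0))
  sort(unique(unlist(lapply(x@semiCurves, function(cv)
    cv[-c(1L, length(cv))]))))
})
setMethod("fixedIndices", "LandmarkScheme", function(x) x@fixedIndices)
setMethod("semiCurves", "LandmarkScheme", function(x) x@semiCurves)
setMethod("shapeCoords", "ShapeSet", function(x) x@coords)
setMethod("sampleInfo", "ShapeSet", function(x) x@info)
setMethod("landmarkScheme", "ShapeSet", function(x) x@scheme)
setMethod("centroidSizes", "AlignedShapeSet", function(x) x@centroidSizes)
setMethod("consensusShape", "AlignedShapeSet", function(x) x@consensus)
setMethod("isConverged", "AlignedShapeSet", function(x) x@converged)
setMethod("femininityTable", "FemininityScores", function(x) x@scores)

#' Number of samples in a ShapeSet
#' @param x a [ShapeSet-class].
#' @return integer sample count.
#' @export
setMethod("length", "ShapeSet", function(x) dim(x@coords)[1])

#' Subset a ShapeSet by sample
#'
#' @param x a [ShapeSet-class] (or [AlignedShapeSet-class]; subsetting an
#'   aligned set returns a plain ShapeSet since the consensus and
#'   convergence bookkeeping no longer apply).
#' @param i sample index vector.
#' @param j,...,drop ignored.
#' @return a [ShapeSet-class].
#' @export
setMethod("[", "ShapeSet", function(x, i, j, ..., drop = FALSE) {
  new("ShapeSet",
      coords = x@coords[i, , , drop = FALSE],
      info = x@info[i, , drop = FALSE],
      scheme = x@scheme)
})

setMethod("show", "LandmarkScheme", function(object) {
  cat("LandmarkScheme:", object@nTotal, "points (",
      length(object@fixedIndices), "fixed,",
      length(semiIndices(object)), "semi-landmarks on",
      length(object@semiCurves), "curves )\n")
})

setMethod("show", "ShapeSet", function(object) {
  d <- dim(object@coords)
  cat(class(object), "with", d[1], "samples x", d[2], "landmarks (2-D)\n")
  tab <- table(object@info$sex, useNA = "ifany")
  cat("  sex:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "AlignedShapeSet", function(object) {
  callNextMethod()
  cat("  superimposed in", object@nIterations, "iterations; converged:",
      object@converged, "\n")
})

setMethod("show", "FemininityScores", function(object) {
  s <- object@scores
  cat("FemininityScores for", nrow(s), "individuals;",
      sum(!is.na(s$z_partner)), "with subsample z-scores\n")
})

setMethod("show", "PermutationTestResult", function(object) {
  cat("Distance-based permutation MANOVA (", object@nPermutations,
      "permutations )\n")
  if (object@flagged) { cat("  test undefined (degenerate input)\n"); return(invisible(NULL)) }
  tab <- data.frame(SS = object@ss,
    VarExpl = c(object@varianceExplained,
                1 - sum(object@varianceExplained)),
    F = c(object@pseudoF, NA)[seq_along(object@ss)],
    p = c(object@pPerm, NA)[seq_along(object@ss)])
  print(round(tab, 4))
})

setMethod("show", "KappaResult", function(object) {
  cat(sprintf("Fleiss' kappa = %.3f (z = %.2f, p = %.3g) over %d items x %d ratings\n",
              object@kappa, object@z, object@p, object@nItems,
              object@nRatings))
})

setMethod("show", "GEEResult", function(object) {
  cat("GEE (", object@family, ",", object@workingCorrelation,
      "working correlation;", object@nClusters, "clusters,", object@nObs,
      "observations )\n")
  print(round(data.frame(B = object@coefficients, robustSE = object@robustSE,
                         WaldX2 = object@waldX2, p = object@p), 4))
})

setMethod("show", "MAResult", function(object) {
  cat(sprintf("Major-axis regression: slope = %.4f, intercept = %.4f, R2 = %.3f, p = %.3g (n = %d)\n",
              object@slope, object@intercept, object@rSquared, object@p,
              object@n))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s = %.4f%s, p = %.4g\n", object@statisticName,
              object@statistic,
              if (is.na(object@df)) "" else sprintf(" (df = %g)", object@df),
              object@p))
})
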