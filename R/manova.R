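#' Run code under a temporary RNG seed
#'
#' Evaluates an expression with the global RNG seeded to `seed`, restoring
#' the previous RNG state afterwards; with `seed = NULL` the expression
#' runs under the current RNG state.
#'
#' @param seed integer or NULL.
#' @param expr expression.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Gower-centered inner-product matrix from Euclidean distances on the rows
# of a response matrix: G = C (-0.5 D^2) C with C the centering matrix.
.gowerG <- function(responses) {
  responses <- as.matrix(responses)
  d2 <- .pairwiseR2(responses, responses)
  d2[d2 < 0] <- 0
  A <- -0.5 * d2
  C <- diag(nrow(A)) - 1 / nrow(A)
  C %*% A %*% C
}

# sequential hat matrices for factors entered in column order
.seqHats <- function(factors) {
  n <- nrow(factors)
  hats <- list(); dfs <- numeric(0)
  prevRank <- 1
  for (k in seq_len(ncol(factors))) {
    Xk <- stats::model.matrix(~ ., data = factors[, seq_len(k), drop = FALSE])
    q <- qr(Xk)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[k]] <- Q %*% t(Q)
    dfs[k] <- q$rank - prevRank
    prevRank <- q$rank
  }
  list(hats = hats, dfs = dfs, rankFull = prevRank)
}

# sequential SS of each factor given hat matrices and a (possibly permuted)
# Gower matrix; G must be double-centered so the intercept term vanishes
.seqSS <- function(hats, G) {
  tr <- vapply(hats, function(H) sum(H * G), 0)
  c(tr[1], diff(tr))
}

#' Distance-based permutation MANOVA (sequential decomposition)
#'
#' Partitions the total sum of squared Euclidean distances among
#' multivariate responses (e.g. flattened Procrustes coordinates) by the
#' predictors of `factors`, entered sequentially in column order, using the
#' Gower-centered distance decomposition. Significance of each factor's
#' pseudo-F is assessed by permuting the observation labels (raw
#' observations, not residuals) and recomputing the full sequential
#' decomposition.
#'
#' @param responses numeric matrix n x q (rows are samples), or an
#'   [AlignedShapeSet-class] whose coordinates are flattened.
#' @param factors data.frame of predictors (categorical or continuous);
#'   column order is the entry order of the sequential decomposition.
#' @param nPerm number of random permutations (default 999). The p-value is
#'   `(exceedances + 1) / (nPerm + 1)`.
#' @param seed integer seed for the permutations, recorded in the result.
#' @param permutations optional integer matrix whose rows are explicit
#'   permutations of `1:n` (e.g. an exhaustive enumeration, identity
#'   included); overrides `nPerm`, and the p-value is then the plain
#'   fraction of rows with `F* >= F`.
#' @return a [PermutationTestResult-class]. With constant responses the
#'   result is flagged and p-values are NA.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(40), 10)
#' g <- data.frame(group = rep(c("a", "b"), each = 5))
#' permutationManova(y, g, nPerm = 199, seed = 1)
#' @export
permutationManova <- function(responses, factors, nPerm = 999, seed = NULL,
                              permutations = NULL) {
  if (is(responses, "AlignedShapeSet")) responses <- flattenShapes(responses)
  responses <- as.matrix(responses)
  n <- nrow(responses)
  stopifnot(n >= 2, nrow(factors) == n)
  factors <- as.data.frame(factors)
  G <- .gowerG(responses)
  ssTotal <- sum(diag(G))
  sh <- .seqHats(factors)
  fnames <- colnames(factors)
  if (ssTotal < 1e-12) {
    z <- stats::setNames(rep(0, length(fnames)), fnames)
    return(new("PermutationTestResult", factorNames = fnames,
               ss = c(z, Residual = 0), df = c(sh$dfs, n - sh$rankFull),
               varianceExplained = z, pseudoF = z + NA,
               pPerm = z + NA, nPermutations = 0L,
               seed = NA_integer_, nSamples = as.integer(n), flagged = TRUE))
  }
  ss <- .seqSS(sh$hats, G)
  dfRes <- n - sh$rankFull
  ssRes <- ssTotal - sum(ss)
  Fobs <- (ss / sh$dfs) / (ssRes / dfRes)
  if (!is.null(permutations)) {
    permutations <- as.matrix(permutations)
    Fstar <- apply(permutations, 1, function(pm) {
      Gp <- G[pm, pm]
      ssp <- .seqSS(sh$hats, Gp)
      (ssp / sh$dfs) / ((ssTotal - sum(ssp)) / dfRes)
    })
    Fstar <- matrix(Fstar, nrow = length(Fobs))
    pPerm <- rowMeans(Fstar >= Fobs - 1e-12)
    nP <- nrow(permutations)
    seedUsed <- NA_integer_
  } else {
    exceed <- withSeed(seed, {
      ex <- rep(0, length(Fobs))
      for (b in seq_len(nPerm)) {
        pm <- sample.int(n)
        Gp <- G[pm, pm]
        ssp <- .seqSS(sh$hats, Gp)
        Fp <- (ssp / sh$dfs) / ((ssTotal - sum(ssp)) / dfRes)
        ex <- ex + (Fp >= Fobs - 1e-12)
      }
      ex
    })
    pPerm <- (exceed + 1) / (nPerm + 1)
    nP <- nPerm
    seedUsed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  }
  names(ss) <- fnames
  new("PermutationTestResult", factorNames = fnames,
      ss = c(ss, Residual = ssRes),
      df = stats::setNames(c(sh$dfs, dfRes), c(fnames, "Residual")),
      varianceExplained = stats::setNames(ss / ssTotal, fnames),
      pseudoF = stats::setNames(Fobs, fnames),
      pPerm = stats::setNames(pPerm, fnames),
      nPermutations = as.integer(nP), seed = seedUsed,
      nSamples = as.integer(n), flagged = FALSE)
}

#' Flatten an aligned shape set to a response matrix
#'
#' @param aligned an [AlignedShapeSet-class] (or n x p x 2 array).
#' @return numeric matrix n x 2p (x-coordinates then y-coordinates).
#' @export
flattenShapes <- function(aligned) {
  co <- if (is(aligned, "ShapeSet")) shapeCoords(aligned) else aligned
  matrix(co, nrow = dim(co)[1])
}

#' Inter-observer repeatability of digitized shapes
#'
#' The ratio of the among-individual variance component to the sum of the
#' among-individual and measurement-error components, from the
#' distance-based one-way decomposition by individual (the same sum-of-
#' squares machinery as [permutationManova()]): with r replicates per
#' individual, `sigma2_among = (MS_among - MS_within) / r`,
#' `sigma2_err = MS_within`, and the repeatability is
#' `sigma2_among / (sigma2_among + sigma2_err)`, clamped to [0, 1].
#'
#' @param aligned an [AlignedShapeSet-class] (individual and observer ids
#'   taken from its metadata) or a numeric response matrix.
#' @param individualIds vector of individual ids, one per row; defaults to
#'   the set's `individual_id` column.
#' @return numeric in [0, 1].
#' @export
repeatability <- function(aligned, individualIds = NULL) {
  if (is(aligned, "AlignedShapeSet")) {
    if (is.null(individualIds)) individualIds <- sampleInfo(aligned)$individual_id
    responses <- flattenShapes(aligned)
  } else responses <- as.matrix(aligned)
  ids <- factor(individualIds)
  reps <- table(ids)
  if (length(unique(reps)) != 1)
    stop("each individual must be digitized the same number of times")
  r <- unname(reps[1])
  if (r < 2) stop("repeatability requires at least 2 replicates per individual")
  g <- nlevels(ids); N <- length(ids)
  G <- .gowerG(responses)
  ssTotal <- sum(diag(G))
  Xk <- stats::model.matrix(~ ids)
  q <- qr(Xk)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  ssAmong <- sum((Q %*% t(Q)) * G)
  msAmong <- ssAmong / (g - 1)
  msWithin <- (ssTotal - ssAmong) / (N - g)
  s2a <- (msAmong - msWithin) / r
  min(max(s2a / (s2a + msWithin), 0), 1)
}
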