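#' Discriminant femininity shape scores
#'
#' Two-group Fisher linear discriminant (female vs male) on Procrustes
#' shape coordinates. Because the coordinate dimension (2p) typically
#' exceeds the sample size, the discriminant is computed after projecting
#' the coordinates onto their principal components, retaining components
#' with non-negligible variance up to `min(n - 3, cap at a cumulative
#' variance fraction)`; the discriminant axis is mapped back to coordinate
#' space for visualization. Raw scores are the projections on the
#' discriminant axis, oriented so that the female mean exceeds the male
#' mean (higher = more feminine). Within-sex z-scores over the full sample
#' (`z_full`) are attached; a subsample standardization can be added with
#' [zStandardize()].
#'
#' @param aligned an [AlignedShapeSet-class] (sex taken from its metadata)
#'   or a numeric n x 2p response matrix.
#' @param sex character/factor of "male"/"female", one per sample.
#' @param varianceCap cumulative variance fraction retained by the PCA
#'   reduction (default 0.95).
#' @param maxComponents hard cap on retained components (default n - 3).
#' @return a [FemininityScores-class].
#' @export
ldaFemininity <- function(aligned, sex = NULL, varianceCap = 0.95,
                          maxComponents = NULL) {
  if (is(aligned, "AlignedShapeSet")) {
    if (is.null(sex)) sex <- sampleInfo(aligned)$sex
    ids <- sampleInfo(aligned)$individual_id
    X <- flattenShapes(aligned)
  } else {
    X <- as.matrix(aligned)
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  }
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female' for every sample")
  n <- nrow(X)
  if (length(unique(sex)) < 2)
    stop("both sexes must be present for a two-group discriminant")
  if (min(table(sex)) < 2) stop("need at least 2 samples per sex")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keepVar <- which(pc$sdev > max(pc$sdev) * 1e-8)
  cum <- cumsum(pc$sdev[keepVar]^2) / sum(pc$sdev[keepVar]^2)
  nCap <- if (is.null(maxComponents)) n - 3L else maxComponents
  nKeep <- min(max(which(cum <= varianceCap + 1e-12), 1), nCap,
               length(keepVar))
  Z <- pc$x[, seq_len(nKeep), drop = FALSE]
  isF <- sex == "female"
  muF <- colMeans(Z[isF, , drop = FALSE])
  muM <- colMeans(Z[!isF, , drop = FALSE])
  Sw <- (crossprod(sweep(Z[isF, , drop = FALSE], 2, muF)) +
         crossprod(sweep(Z[!isF, , drop = FALSE], 2, muM))) / (n - 2)
  w <- tryCatch(solve(Sw, muF - muM), error = function(e)
    stop("within-group scatter is singular; reduce varianceCap or ",
         "maxComponents"))
  raw <- as.numeric(Z %*% w)
  if (mean(raw[isF]) <= mean(raw[!isF])) { w <- -w; raw <- -raw }
  axisCoord <- pc$rotation[, seq_len(nKeep), drop = FALSE] %*% w
  axisCoord <- matrix(axisCoord / sqrt(sum(axisCoord^2)), ncol = 2)
  scores <- data.frame(individual_id = ids, sex = sex, raw_score = raw,
                       z_full = NA_real_, z_partner = NA_real_,
                       stringsAsFactors = FALSE)
  for (g in c("male", "female")) {
    sel <- scores$sex == g
    scores$z_full[sel] <- (raw[sel] - mean(raw[sel])) / stats::sd(raw[sel])
  }
  new("FemininityScores", scores = scores, axis = axisCoord)
}

#' Within-group z-standardization of femininity scores
#'
#' Without a subset, recomputes `z_full`: within each sex, raw scores are
#' centered and scaled by that sex's mean and SD over all scored
#' individuals. With a subset of ids (e.g. the stimulus partners), computes
#' `z_partner` for the subset members only, using the subset's own per-sex
#' means and SDs as the standardization base.
#'
#' @param scores a [FemininityScores-class].
#' @param subset optional character vector of individual ids defining the
#'   subsample standardization base.
#' @return the updated [FemininityScores-class].
#' @export
zStandardize <- function(scores, subset = NULL) {
  stopifnot(is(scores, "FemininityScores"))
  s <- scores@scores
  if (is.null(subset)) {
    for (g in unique(s$sex)) {
      sel <- s$sex == g
      sdv <- stats::sd(s$raw_score[sel])
      if (length(which(sel)) < 2 || sdv == 0)
        stop("zero SD or too few members in group '", g, "'")
      s$z_full[sel] <- (s$raw_score[sel] - mean(s$raw_score[sel])) / sdv
    }
  } else {
    inset <- s$individual_id %in% subset
    if (!any(inset)) stop("no scored individuals in the given subset")
    for (g in unique(s$sex[inset])) {
      sel <- inset & s$sex == g
      sdv <- stats::sd(s$raw_score[sel])
      if (length(which(sel)) < 2 || sdv == 0)
        stop("zero SD or too few subset members in group '", g, "'")
      s$z_partner[sel] <- (s$raw_score[sel] - mean(s$raw_score[sel])) / sdv
    }
  }
  initialize(scores, scores = s)
}
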