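#' Run the morphometric half of the analysis
#'
#' Executes, in order: sample exclusions (beard / head deviation / origin),
#' Generalized Procrustes superimposition with sliding semi-landmarks,
#' distance-based permutation MANOVA of shape on sex (and sequentially on
#' age then sex when ages are available), two-group discriminant femininity
#' scores with within-sex z-standardization (full sample and, when
#' `partnerIds` is given, the partner subsample), inter-observer
#' repeatability when replicate digitizations are present, and dimorphism
#' visualizations (sex mean shapes, 3x exaggerations, deformation grids).
#'
#' @param shapes a [ShapeSet-class] (possibly with replicate
#'   digitizations).
#' @param allowedOrigins passed to [applyMorphometricExclusions()].
#' @param partnerIds optional ids defining the partner-subsample
#'   standardization.
#' @param nPerm permutations for the MANOVA (default 10000).
#' @param seed integer seed for the permutations.
#' @param slide slide semi-landmarks (default TRUE).
#' @param exaggeration exaggeration factor for visualization (default 3).
#' @return list with elements `aligned`, `exclusions`, `manovaSex`,
#'   `manovaAgeSex`, `scores`, `repeatability` (NA without replicates),
#'   `consensus`, `meanShapes` (per sex, k = 1 and exaggerated), `grids`.
#' @export
runMorphometrics <- function(shapes, allowedOrigins = NULL,
                             partnerIds = NULL, nPerm = 10000,
                             seed = 1L, slide = TRUE, exaggeration = 3) {
  excl <- applyMorphometricExclusions(shapes, allowedOrigins)
  kept <- excl$shapes
  info <- sampleInfo(kept)
  # repeatability from replicate digitizations, when present
  rept <- NA_real_
  if (length(unique(info$observer_id)) > 1) {
    reps <- table(info$individual_id)
    replicated <- names(reps)[reps == max(reps)]
    if (max(reps) >= 2 && length(replicated) >= 2) {
      sub <- kept[which(info$individual_id %in% replicated)]
      alSub <- gpa(sub, slide = slide)
      rept <- repeatability(alSub)
    }
  }
  # main analysis: one digitization per individual (first observer seen)
  first <- !duplicated(info$individual_id)
  main <- kept[which(first)]
  aligned <- gpa(main, slide = slide)
  minfo <- sampleInfo(aligned)
  flat <- flattenShapes(aligned)
  manovaSex <- permutationManova(flat, data.frame(sex = minfo$sex),
                                 nPerm = nPerm, seed = seed)
  manovaAgeSex <- if (all(is.finite(minfo$age)))
    permutationManova(flat, data.frame(age = minfo$age, sex = minfo$sex),
                      nPerm = nPerm, seed = seed) else NULL
  scores <- ldaFemininity(aligned)
  if (!is.null(partnerIds)) scores <- zStandardize(scores, subset = partnerIds)
  cons <- consensusShape(aligned)
  co <- shapeCoords(aligned)
  meanShapes <- list()
  grids <- list()
  for (g in c("female", "male")) {
    gm <- apply(co[minfo$sex == g, , , drop = FALSE], c(2, 3), mean)
    meanShapes[[g]] <- gm
    meanShapes[[paste0(g, "_x", exaggeration)]] <-
      exaggerateShape(cons, gm, exaggeration)
    grids[[g]] <- deformationGrid(cons, gm)
    grids[[paste0(g, "_x", exaggeration)]] <-
      deformationGrid(cons, meanShapes[[paste0(g, "_x", exaggeration)]])
  }
  list(aligned = aligned, exclusions = excl$removed, manovaSex = manovaSex,
       manovaAgeSex = manovaAgeSex, scores = scores, repeatability = rept,
       consensus = cons, meanShapes = meanShapes, grids = grids)
}

#' Run the behavioral half of the analysis
#'
#' Reproduces the Trust-Game statistics as machine-readable tables:
#' acquaintance exclusions, trust/fair-return rate summaries, the
#' trust-trustworthiness association curves, per-interaction switch and
#' shift records with their per-video summaries, Fleiss-kappa consistency
#' of the five trust decisions and of the fair/non-fair binarized returns,
#' GEE models (switch direction against decider and partner sex; switch
#' direction against sexes and partner femininity; linear return shifts
#' against the same predictors), major-axis regressions of per-video
#' trustworthiness shifts on trust shifts by rater and partner sex, and,
#' when scores are given, regressions of own trustworthiness on own facial
#' femininity (anonymous: ordinary linear regression per sex;
#' personalized: linear GEE per sex and partner sex).
#'
#' @param interactions interaction table (see [validateInteractions()]).
#' @param scores optional [FemininityScores-class]; partner femininity
#'   uses `z_partner`, own femininity `z_full`.
#' @return list of result tables and fitted models (see Details).
#' @export
runBehavior <- function(interactions, scores = NULL) {
  excl <- excludeAcquainted(interactions)
  ia <- excl$interactions
  rates <- summarizeRates(ia)
  curve <- associationCurve(ia)
  shifts <- shiftRecords(ia)
  videoSummary <- videoShiftSummary(shifts)
  ratings <- decisionRatings(interactions)  # consistency uses complete cases
  kappaTrust <- fleissKappa(ratings$trust, categories = c(0, 1))
  kappaFair <- fleissKappa(ratings$fairness, categories = c(0, 1))
  switches <- shifts[shifts$trust_switch != 0, ]
  switchCounts <- c(to_trust = sum(shifts$trust_switch == 1),
                    to_distrust = sum(shifts$trust_switch == -1))
  geeSwitchSex <- NULL
  if (nrow(switches) >= 8 && length(unique(switches$subject_id)) >= 2) {
    sw <- data.frame(
      toTrust = as.integer(switches$trust_switch == 1),
      dmMale = as.integer(switches$subject_sex == "male"),
      partnerMale = as.integer(switches$partner_sex == "male"),
      id = switches$subject_id)
    # the switch direction is constant within a subject (it is fixed by
    # the anonymous baseline), so the switch models use the independence
    # working correlation; robust SEs still account for the clustering
    geeSwitchSex <- tryCatch(
      geeFit(toTrust ~ dmMale * partnerMale, sw, id = "id",
             family = "binomial", corstr = "independence"),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "degenerateFit"))
  }
  geeSwitchFem <- geeReturnShift <- maTables <- ownFem <- NULL
  if (!is.null(scores)) {
    ztab <- femininityTable(scores)
    femOf <- function(id, col) ztab[[col]][match(id, ztab$individual_id)]
    shifts$partner_fem <- femOf(shifts$partner_id, "z_partner")
    shf <- shifts[is.finite(shifts$partner_fem), ]
    swf <- shf[shf$trust_switch != 0, ]
    if (nrow(swf) >= 12) {
      d2 <- data.frame(toTrust = as.integer(swf$trust_switch == 1),
                       dmMale = as.integer(swf$subject_sex == "male"),
                       partnerMale = as.integer(swf$partner_sex == "male"),
                       fem = swf$partner_fem, id = swf$subject_id)
      geeSwitchFem <- tryCatch(
        geeFit(toTrust ~ dmMale + partnerMale + fem + dmMale:fem +
                 partnerMale:fem, d2, id = "id", family = "binomial",
               corstr = "independence"),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "degenerateFit"))
    }
    d3 <- data.frame(shift = shf$return_shift,
                     dmMale = as.integer(shf$subject_sex == "male"),
                     partnerMale = as.integer(shf$partner_sex == "male"),
                     fem = shf$partner_fem, id = shf$subject_id)
    if (nrow(d3) >= 12)
      geeReturnShift <- tryCatch(
        geeFit(shift ~ dmMale + partnerMale + fem + dmMale:fem, d3,
               id = "id", family = "gaussian"),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "degenerateFit"))
  }
  # per-video major-axis regressions: trustworthiness shift on trust shift
  maTables <- list()
  for (rs in unique(videoSummary$rater_sex))
    for (ps in unique(videoSummary$partner_sex)) {
      sel <- videoSummary$rater_sex == rs & videoSummary$partner_sex == ps
      if (sum(sel) >= 3) {
        fit <- tryCatch(majorAxis(videoSummary$trust_shift[sel],
                                  videoSummary$return_shift[sel]),
                        error = function(e) NULL)
        if (!is.null(fit))
          maTables[[paste(rs, "raters x", ps, "videos")]] <- fit
      }
    }
  if (!is.null(scores)) {
    ztab <- femininityTable(scores)
    ownFem <- list()
    anon <- ia[ia$setting == "anon", ]
    anon$z <- ztab$z_full[match(anon$subject_id, ztab$individual_id)]
    pers <- ia[!is.na(ia$partner_id), ]
    pers$z <- ztab$z_full[match(pers$subject_id, ztab$individual_id)]
    for (sx in c("female", "male")) {
      sub <- anon[anon$subject_sex == sx & is.finite(anon$z), ]
      if (nrow(sub) >= 3) {
        lmfit <- stats::lm(return_amount ~ z, data = sub)
        ownFem[[paste0(sx, "_anon")]] <-
          c(B = unname(stats::coef(lmfit)[2]),
            R2 = summary(lmfit)$r.squared,
            p = summary(lmfit)$coefficients[2, 4], N = nrow(sub))
      }
      for (ps in c("female", "male")) {
        sub <- pers[pers$subject_sex == sx & pers$partner_sex == ps &
                      is.finite(pers$z), ]
        if (nrow(sub) >= 8 && length(unique(sub$subject_id)) >= 2) {
          fit <- tryCatch(geeFit(return_amount ~ z, sub, id = sub$subject_id,
                                 family = "gaussian"),
                          error = function(e) NULL)
          if (!is.null(fit)) ownFem[[paste0(sx, "_vs_", ps)]] <- fit
        }
      }
    }
  }
  list(nAcquaintedRemoved = excl$nRemoved, interactions = ia,
       rates = rates, associationCurve = curve, shifts = shifts,
       switchCounts = switchCounts, videoSummary = videoSummary,
       kappaTrust = kappaTrust, kappaFair = kappaFair,
       geeSwitchSex = geeSwitchSex, geeSwitchFem = geeSwitchFem,
       geeReturnShift = geeReturnShift, majorAxis = maTables,
       ownFemininity = ownFem)
}

#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic cohort (faces and Trust-Game behavior with known
#' ground truth), runs the morphometric stage to obtain partner femininity
#' scores from the simulated faces themselves (the behavioral and
#' morphometric halves are integration-tested together, scores are never
#' injected), then runs the behavioral stage. Also fits the
#' population-averaged personalized-trust model
#' `trust ~ partner sex + partner femininity + decider sex x femininity`
#' whose coefficients estimate the generator's ground-truth effects.
#'
#' @param faceConfig a [faceSimConfig()]; the face sample sizes must cover
#'   the stimulus partners of `behaviorConfig`.
#' @param behaviorConfig a [behaviorSimConfig()].
#' @param nPerm permutations for the shape MANOVA.
#' @param seed integer master seed (overrides the config seeds).
#' @return list with `morpho`, `behavior`, `trustModel` (GEE fit on
#'   personalized trust), `groundTruth`, `faces`, `interactions`.
#' @export
runTrustPipeline <- function(faceConfig = faceSimConfig(),
                             behaviorConfig = behaviorSimConfig(),
                             nPerm = 999, seed = 1L) {
  faceConfig$seed <- as.integer(seed)
  behaviorConfig$seed <- as.integer(seed + 1)
  nV <- behaviorConfig$nVideosPerSex
  faces <- generateFaces(faceConfig)
  partnerIds <- c(paste0("m", sprintf("%03d", seq_len(nV))),
                  paste0("f", sprintf("%03d", seq_len(nV))))
  morpho <- runMorphometrics(faces, partnerIds = partnerIds, nPerm = nPerm,
                             seed = seed)
  ztab <- femininityTable(morpho$scores)
  pf <- data.frame(partner_id = ztab$individual_id[!is.na(ztab$z_partner)],
                   fem_z = ztab$z_partner[!is.na(ztab$z_partner)])
  beh <- generateBehavior(behaviorConfig, partnerFemZ = pf)
  behavior <- runBehavior(beh$interactions, scores = morpho$scores)
  pers <- behavior$interactions
  pers <- pers[!is.na(pers$partner_id), ]
  pers$fem <- pf$fem_z[match(pers$partner_id, pf$partner_id)]
  d <- data.frame(trust = as.integer(pers$trust_decision),
                  partnerMale = as.integer(pers$partner_sex == "male"),
                  dmMale = as.integer(pers$subject_sex == "male"),
                  fem = pers$fem, id = pers$subject_id)
  trustModel <- geeFit(trust ~ partnerMale + fem + dmMale:fem, d,
                       id = "id", family = "binomial")
  list(morpho = morpho, behavior = behavior, trustModel = trustModel,
       groundTruth = c(beh$groundTruth, delta = faceConfig$delta),
       faces = faces, interactions = beh$interactions)
}
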