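#' Configuration for the synthetic Trust-Game generator
#'
#' Defaults emulate the study conditions of the behavioral experiment: 176
#' subjects (89 males, 87 females), 10 stimulus videos per sex, an
#' anonymous trust rate near 70% with substantial between-subject
#' consistency, a female-partner boost to personalized trust, a negative
#' effect of partner facial femininity opposed in male deciders, return
#' amounts on the 0/50/75/100 grid with roughly 46% fair (100-point)
#' returns and a mild personalization drift toward lower returns, and a
#' small acquaintance rate (about 5 in 704 displays).
#'
#' @param nMale,nFemale subjects per sex.
#' @param nVideosPerSex stimulus videos per sex (>= 2).
#' @param alphaTrust baseline log-odds of anonymous trust.
#' @param thetaSd SD of the subject-level trust propensity.
#' @param betaPersonal log-odds offset common to all personalized games;
#'   with the default half-magnitude of `betaPartnerSex` it centers the
#'   partner-sex contrast on the anonymous baseline (female partners raise
#'   trust, male partners lower it).
#' @param betaPartnerSex log-odds effect of a MALE partner on personalized
#'   trust (negative: female partners elicit more trust).
#' @param betaFem log-odds effect of partner facial femininity (z-score)
#'   for female deciders.
#' @param betaFemByDmSex interaction: additional femininity slope for male
#'   deciders.
#' @param returnCuts latent cutpoints separating returns 0|50|75|100.
#' @param fairSd SD of the subject-level return (fairness) propensity.
#' @param returnDrift latent location shift of returns under
#'   personalization (negative: returns decline).
#' @param propAcquainted probability a personalized display is with an
#'   acquaintance.
#' @param seed integer seed.
#' @return a list of class `BehaviorSimConfig`.
#' @export
behaviorSimConfig <- function(nMale = 89, nFemale = 87, nVideosPerSex = 10,
                              alphaTrust = 1.85, thetaSd = 3.0,
                              betaPersonal = 0.95,
                              betaPartnerSex = -1.5, betaFem = -1.0,
                              betaFemByDmSex = 0.8,
                              returnCuts = c(-12.5, -4.6, -0.4),
                              fairSd = 10.0, returnDrift = -1.2,
                              propAcquainted = 5 / 704, seed = 1L) {
  stopifnot(nVideosPerSex >= 2, all(diff(returnCuts) > 0), thetaSd >= 0,
            fairSd >= 0)
  structure(list(nMale = nMale, nFemale = nFemale,
                 nVideosPerSex = nVideosPerSex, alphaTrust = alphaTrust,
                 thetaSd = thetaSd, betaPersonal = betaPersonal,
                 betaPartnerSex = betaPartnerSex,
                 betaFem = betaFem, betaFemByDmSex = betaFemByDmSex,
                 returnCuts = returnCuts, fairSd = fairSd,
                 returnDrift = returnDrift,
                 propAcquainted = propAcquainted, seed = as.integer(seed)),
            class = "BehaviorSimConfig")
}

.cutReturn <- function(latent, cuts)
  RETURN_LEVELS[findInterval(latent, cuts) + 1]

#' Generate synthetic five-game Trust-Game decisions
#'
#' Each subject plays one anonymous and four personalized games (two
#' same-sex, two opposite-sex stimulus videos, assigned at random without
#' replacement, never their own video). Trust decisions are Bernoulli with
#' log-odds `alpha + theta_i` (anonymous) plus
#' `betaPartnerSex * male(partner) + betaFem * femz +
#' betaFemByDmSex * male(subject) * femz` (personalized). Returns follow a
#' cumulative-logit model over the ordered grid 0/50/75/100: a latent
#' `u_i + drift * personalized + logistic noise` is cut at `returnCuts`,
#' so personalization shifts the whole return distribution by
#' `returnDrift`. The first `nVideosPerSex` subjects of each sex serve as
#' the stimulus partners (so partner anonymous decisions exist for payoff
#' settlement). Deterministic given the config seed.
#'
#' @param config a [behaviorSimConfig()].
#' @param partnerFemZ data.frame with columns `partner_id`, `fem_z` giving
#'   the femininity z-scores of the stimulus partners, or NULL to draw
#'   them standard-normal within sex. Ids must match
#'   `m001..` / `f001..` when supplied by the face pipeline.
#' @return list with `interactions` (validated interaction table,
#'   anonymous and personalized rows), `partners` (data.frame of video
#'   partners with their femininity z-scores) and `groundTruth` (all
#'   generating parameters).
#' @export
generateBehavior <- function(config, partnerFemZ = NULL) {
  nM <- config$nMale; nF <- config$nFemale
  nV <- config$nVideosPerSex
  stopifnot(nM >= nV + 2, nF >= nV + 2)
  sex <- rep(c("male", "female"), c(nM, nF))
  ids <- paste0(ifelse(sex == "male", "m", "f"),
                sprintf("%03d", c(seq_len(nM), seq_len(nF))))
  videoIds <- c(paste0("m", sprintf("%03d", seq_len(nV))),
                paste0("f", sprintf("%03d", seq_len(nV))))
  videoSex <- rep(c("male", "female"), each = nV)
  withSeed(config$seed, {
    if (is.null(partnerFemZ)) {
      femz <- stats::setNames(stats::rnorm(2 * nV), videoIds)
    } else {
      femz <- stats::setNames(partnerFemZ$fem_z,
                              as.character(partnerFemZ$partner_id))
      if (!all(videoIds %in% names(femz)))
        stop("partnerFemZ lacks scores for: ",
             paste(setdiff(videoIds, names(femz)), collapse = ", "))
      femz <- femz[videoIds]
    }
    nInd <- nM + nF
    theta <- stats::rnorm(nInd, sd = config$thetaSd)
    u <- stats::rnorm(nInd, sd = config$fairSd)
    # stimulus assignment: 2 same-sex + 2 opposite-sex videos per subject,
    # never the subject's own video
    vids <- t(vapply(seq_len(nInd), function(i) {
      ssPool <- setdiff(videoIds[videoSex == sex[i]], ids[i])
      osPool <- videoIds[videoSex != sex[i]]
      c(sample(ssPool, 2), sample(osPool, 2))
    }, character(4)))
    anon <- data.frame(
      subject_id = ids, subject_sex = sex, partner_id = NA_character_,
      setting = "anon", partner_sex = NA_character_, acquainted = FALSE,
      trust_decision = stats::runif(nInd) <
        stats::plogis(config$alphaTrust + theta),
      return_amount = .cutReturn(u + stats::rlogis(nInd),
                                 config$returnCuts),
      stringsAsFactors = FALSE)
    subj <- rep(seq_len(nInd), each = 4)
    vid <- as.vector(t(vids))
    pSex <- videoSex[match(vid, videoIds)]
    z <- unname(femz[vid])
    eta <- config$alphaTrust + theta[subj] + config$betaPersonal +
      config$betaPartnerSex * (pSex == "male") + config$betaFem * z +
      config$betaFemByDmSex * (sex[subj] == "male") * z
    pers <- data.frame(
      subject_id = ids[subj], subject_sex = sex[subj], partner_id = vid,
      setting = rep(c("SS1", "SS2", "OS1", "OS2"), nInd),
      partner_sex = pSex,
      acquainted = stats::runif(4 * nInd) < config$propAcquainted,
      trust_decision = stats::runif(4 * nInd) < stats::plogis(eta),
      return_amount = .cutReturn(
        u[subj] + config$returnDrift + stats::rlogis(4 * nInd),
        config$returnCuts),
      stringsAsFactors = FALSE)
    all <- rbind(anon, pers)
    all <- all[order(match(all$subject_id, ids),
                     match(all$setting, c("anon", "SS1", "SS2",
                                          "OS1", "OS2"))), ]
    rownames(all) <- NULL
    interactions <- validateInteractions(all)
    list(interactions = interactions,
         partners = data.frame(partner_id = videoIds, sex = videoSex,
                               fem_z = unname(femz)),
         groundTruth = list(
           alphaTrust = config$alphaTrust, thetaSd = config$thetaSd,
           betaPersonal = config$betaPersonal,
           betaPartnerSex = config$betaPartnerSex,
           betaFem = config$betaFem,
           betaFemByDmSex = config$betaFemByDmSex,
           returnCuts = config$returnCuts, fairSd = config$fairSd,
           returnDrift = config$returnDrift, seed = config$seed))
  })
}
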