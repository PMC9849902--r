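#' Configuration for the synthetic face generator
#'
#' Defaults emulate the study conditions of the facial-shape analysis: 145
#' analyzed faces (72 males, 73 females), a sexual-dimorphism magnitude
#' calibrated so that sex explains about 7% of total shape variance after
#' superimposition, individual variation dominating digitization error so
#' that two-observer repeatability is about 0.96, and one observer (set
#' `nObservers = 2` for a replicated-digitization study).
#'
#' @param nMale,nFemale individuals per sex.
#' @param delta dimorphism magnitude: the full male-female mean difference
#'   along [dimorphismField()], in template units.
#' @param sigmaIndividual SD of per-point isotropic individual variation
#'   (template units).
#' @param sigmaDigitization SD of per-point observer digitization error.
#' @param nObservers replicate digitizations per individual.
#' @param seed integer seed.
#' @return a list of class `FaceSimConfig`.
#' @export
faceSimConfig <- function(nMale = 72, nFemale = 73, delta = 0.275,
                          sigmaIndividual = 0.03,
                          sigmaDigitization = 0.004,
                          nObservers = 1, seed = 1L) {
  stopifnot(sigmaIndividual >= 0, sigmaDigitization >= 0, delta >= 0)
  structure(list(nMale = nMale, nFemale = nFemale, delta = delta,
                 sigmaIndividual = sigmaIndividual,
                 sigmaDigitization = sigmaDigitization,
                 nObservers = nObservers, seed = as.integer(seed)),
            class = "FaceSimConfig")
}

#' Generate synthetic landmark configurations with known dimorphism
#'
#' Individual i of sex s gets coordinates
#' `template + s * delta/2 * field + individual deviation`, with
#' `s = +1` for males and `-1` for females, per-point isotropic normal
#' individual deviations (`sigmaIndividual`), and, per observer replicate,
#' additional digitization noise (`sigmaDigitization`). Every digitized
#' sample is then hit with a random similarity transform (rotation,
#' scaling, translation) so that superimposition is genuinely exercised.
#' Deterministic given the config seed.
#'
#' @param config a [faceSimConfig()].
#' @return a [ShapeSet-class] with `nObservers` rows per individual and
#'   metadata (`individual_id`, `sex`, `age`, `origin`, `observer_id`,
#'   flags all FALSE).
#' @export
generateFaces <- function(config) {
  tpl <- faceTemplate()
  field <- dimorphismField()
  scheme <- defaultLandmarkScheme()
  p <- nrow(tpl)
  nInd <- config$nMale + config$nFemale
  sex <- rep(c("male", "female"), c(config$nMale, config$nFemale))
  ids <- paste0(ifelse(sex == "male", "m", "f"),
                sprintf("%03d", c(seq_len(config$nMale),
                                  seq_len(config$nFemale))))
  withSeed(config$seed, {
    age <- sample(18:30, nInd, replace = TRUE)
    n <- nInd * config$nObservers
    coords <- array(NA_real_, c(n, p, 2))
    info <- data.frame(individual_id = rep(ids, each = config$nObservers),
                       sex = rep(sex, each = config$nObservers),
                       age = rep(age, each = config$nObservers),
                       origin = "Dutch",
                       observer_id = paste0("obs", rep(seq_len(config$nObservers),
                                                       nInd)),
                       beard = FALSE, head_deviation = FALSE,
                       stringsAsFactors = FALSE)
    k <- 0
    for (i in seq_len(nInd)) {
      s <- if (sex[i] == "male") 1 else -1
      base <- tpl + s * config$delta / 2 * field +
        matrix(stats::rnorm(p * 2, sd = config$sigmaIndividual), p, 2)
      for (o in seq_len(config$nObservers)) {
        k <- k + 1
        sh <- base + matrix(stats::rnorm(p * 2, sd = config$sigmaDigitization),
                            p, 2)
        theta <- stats::runif(1, -pi, pi)
        sc <- exp(stats::runif(1, -0.3, 0.3))
        tr <- stats::runif(2, -2, 2)
        coords[k, , ] <- sweep(sc * sh %*% .rotMat(theta), 2, tr, "+")
      }
    }
    new("ShapeSet", coords = coords, info = info, scheme = scheme)
  })
}

# mean sex variance-explained over replicate simulations at a given delta
.sexR2 <- function(config, nRep, slide = TRUE) {
  mean(vapply(seq_len(nRep), function(r) {
    cfg <- config
    cfg$seed <- as.integer((config$seed * 1000L + r) %% .Machine$integer.max)
    faces <- generateFaces(cfg)
    al <- gpa(faces, slide = slide)
    res <- permutationManova(flattenShapes(al),
                             data.frame(sex = sampleInfo(al)$sex), nPerm = 0)
    unname(res@varianceExplained["sex"])
  }, 0))
}

#' Calibrate the dimorphism magnitude to a target variance explained
#'
#' Bisection on `delta` until the mean variance in Procrustes shape
#' explained by sex (over `nRep` replicate simulations at the config's
#' sample sizes) is within `tol` of `targetR2`. Used to pin the simulator
#' to an empirically realistic effect size (about 7% in European faces).
#'
#' @param targetR2 target fraction of shape variance explained by sex,
#'   in (0, 0.5).
#' @param config a [faceSimConfig()]; its `delta` is ignored.
#' @param nRep replicate simulations per probe (default 20).
#' @param tol tolerance on the mean variance explained (default 0.005).
#' @param slide slide semi-landmarks during superimposition (default TRUE).
#' @return the calibrated `delta` (numeric).
#' @export
calibrateDimorphism <- function(targetR2, config = faceSimConfig(),
                                nRep = 20, tol = 0.005, slide = TRUE) {
  stopifnot(targetR2 > 0, targetR2 < 0.5)
  f <- function(delta) {
    cfg <- config; cfg$delta <- delta
    .sexR2(cfg, nRep, slide = slide)
  }
  lo <- 0; hi <- 0.1
  fhi <- f(hi)
  while (fhi < targetR2) {
    if (hi > 4) stop("target variance explained unattainable with these SDs")
    hi <- hi * 2
    fhi <- f(hi)
  }
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - targetR2) <= tol) return(mid)
    if (fm < targetR2) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
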