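RETURN_LEVELS <- c(0, 50, 75, 100)

#' Validate a Trust-Game interaction table
#'
#' Interaction tables hold one row per subject-setting with columns
#' `subject_id`, `subject_sex`, `partner_id` (NA for the anonymous
#' setting), `setting` (one of "anon", "SS1", "SS2", "OS1", "OS2"),
#' `partner_sex` (NA for anon), `acquainted`, `trust_decision` (logical or
#' 0/1), `return_amount` (0, 50, 75 or 100). Checks the structural
#' invariants: permitted return amounts, same-sex settings paired with
#' same-sex partners (and opposite-sex accordingly), and no partner in the
#' anonymous setting.
#'
#' @param interactions data.frame as above.
#' @return the validated data.frame (trust coerced to logical), invisibly
#'   usable; errors describe the first violated invariant.
#' @export
validateInteractions <- function(interactions) {
  need <- c("subject_id", "subject_sex", "partner_id", "setting",
            "partner_sex", "acquainted", "trust_decision", "return_amount")
  miss <- setdiff(need, names(interactions))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- interactions$setting %in% c("anon", "SS1", "SS2", "OS1", "OS2")
  if (!all(ok)) stop("unknown settings: ",
                     paste(unique(interactions$setting[!ok]), collapse = ", "))
  ret <- interactions$return_amount
  if (!all(is.na(ret) | ret %in% RETURN_LEVELS))
    stop("return amounts must be one of ", paste(RETURN_LEVELS, collapse = "/"))
  anon <- interactions$setting == "anon"
  if (any(!is.na(interactions$partner_id[anon])))
    stop("anonymous records must have no partner")
  ss <- grepl("^SS", interactions$setting)
  os <- grepl("^OS", interactions$setting)
  bad <- (ss & interactions$partner_sex != interactions$subject_sex) |
         (os & interactions$partner_sex == interactions$subject_sex)
  if (any(bad, na.rm = TRUE))
    stop("partner sex inconsistent with same-/opposite-sex setting")
  interactions$trust_decision <- as.logical(interactions$trust_decision)
  interactions
}

#' Settle one Trust-Game interaction
#'
#' The trustor holds a 50-point endowment. Keeping it yields payoffs
#' (50, 0); entrusting triples it to 150, of which the trustee returns 0,
#' 50, 75 or 100 points, keeping the rest, so the payoffs are
#' (return, 150 - return). Payoffs always sum to 150 when entrusted and to
#' 50 otherwise.
#'
#' @param entrusted logical (vectorized): did the trustor entrust?
#' @param returned numeric: the trustee's return (0/50/75/100); ignored
#'   (may be NA) when not entrusted.
#' @return data.frame with columns `trustor`, `trustee` (points).
#' @examples
#' settlePayoffs(c(FALSE, TRUE, TRUE), c(NA, 100, 0))
#' @export
settlePayoffs <- function(entrusted, returned) {
  entrusted <- as.logical(entrusted)
  if (any(entrusted & !(returned %in% RETURN_LEVELS)))
    stop("invalid return amount; permitted: ",
         paste(RETURN_LEVELS, collapse = "/"))
  data.frame(trustor = ifelse(entrusted, returned, 50),
             trustee = ifelse(entrusted, 150 - returned, 0))
}

.anonTable <- function(interactions) {
  anon <- interactions[interactions$setting == "anon", ]
  anon[!duplicated(anon$subject_id), ]
}

#' Settle all interactions against the partners' anonymous decisions
#'
#' Decisions were collected without feedback and settled post hoc: each
#' personalized decision is matched against the decision its partner made
#' in the anonymous setting (taken to reflect the partner's behavioral
#' predisposition); anonymous decisions are matched against the anonymous
#' decision of a uniformly chosen random partner (seeded). Returns the
#' per-interaction settlements and cumulative per-subject totals over both
#' roles.
#'
#' @param interactions validated interaction table (see
#'   [validateInteractions()]); every referenced partner must have an
#'   anonymous record.
#' @param seed integer seed for the random anonymous matching.
#' @return list with `settled` (interaction table plus `trustor_payoff`,
#'   `trustee_payoff`, `matched_partner`) and `totals` (per-subject
#'   data.frame with `trustor_total`, `trustee_total`, `total`).
#' @export
matchPayoffs <- function(interactions, seed = 1L) {
  interactions <- validateInteractions(interactions)
  anon <- .anonTable(interactions)
  rownames(anon) <- anon$subject_id
  pers <- !is.na(interactions$partner_id)
  missing <- setdiff(unique(interactions$partner_id[pers]), anon$subject_id)
  if (length(missing))
    stop("partners without an anonymous decision: ",
         paste(missing, collapse = ", "))
  matched <- withSeed(seed, {
    m <- as.character(interactions$partner_id)
    for (i in which(!pers)) {
      pool <- setdiff(anon$subject_id, interactions$subject_id[i])
      m[i] <- pool[sample.int(length(pool), 1)]
    }
    m
  })
  pAnon <- anon[matched, ]
  trustorPay <- settlePayoffs(interactions$trust_decision,
                              pAnon$return_amount)$trustor
  trusteePay <- settlePayoffs(pAnon$trust_decision,
                              interactions$return_amount)$trustee
  settled <- cbind(interactions, trustor_payoff = trustorPay,
                   trustee_payoff = trusteePay, matched_partner = matched)
  totals <- stats::aggregate(
    cbind(trustor_total = trustor_payoff, trustee_total = trustee_payoff) ~
      subject_id, data = settled, FUN = sum)
  totals$total <- totals$trustor_total + totals$trustee_total
  list(settled = settled, totals = totals)
}

#' Exclude interactions with personally acquainted partners
#'
#' Personalized interactions in which the subject reported knowing the
#' partner in person are removed from analysis; anonymous records are
#' never removed. Idempotent.
#'
#' @param interactions interaction table with populated `acquainted`.
#' @return list with `interactions` (retained rows) and `nRemoved`.
#' @export
excludeAcquainted <- function(interactions) {
  drop <- !is.na(interactions$partner_id) & isTRUE_v(interactions$acquainted)
  list(interactions = interactions[!drop, , drop = FALSE],
       nRemoved = sum(drop))
}

.settingClass <- function(setting)
  ifelse(setting == "anon", "Anon",
         ifelse(grepl("^SS", setting), "Pers SS", "Pers OS"))

#' Trust and trustworthiness rate summaries
#'
#' Per subject sex and setting class (anonymous, personalized same-sex,
#' personalized opposite-sex): the percentage of interactions in which the
#' subject entrusted, returned the fair share (100 points) and returned
#' zero; pooled rows (`sex = "all"`, `setting = "all"`) included.
#'
#' @param interactions validated interaction table.
#' @return data.frame with columns `sex`, `setting`, `n`, `pct_trust`,
#'   `pct_fair`, `pct_zero`.
#' @export
summarizeRates <- function(interactions) {
  interactions <- validateInteractions(interactions)
  cls <- .settingClass(interactions$setting)
  one <- function(sel, sexLab, setLab) {
    data.frame(sex = sexLab, setting = setLab, n = sum(sel),
               pct_trust = 100 * mean(interactions$trust_decision[sel]),
               pct_fair = 100 * mean(interactions$return_amount[sel] == 100),
               pct_zero = 100 * mean(interactions$return_amount[sel] == 0))
  }
  rows <- list()
  for (sx in unique(interactions$subject_sex))
    for (st in c("Anon", "Pers SS", "Pers OS")) {
      sel <- interactions$subject_sex == sx & cls == st
      if (any(sel)) rows[[length(rows) + 1]] <- one(sel, sx, st)
    }
  rows[[length(rows) + 1]] <-
    one(rep(TRUE, nrow(interactions)), "all", "all")
  do.call(rbind, rows)
}

#' Association between trust and trustworthiness
#'
#' For each group (subject sex crossed with partner class: anonymous, male
#' partner, female partner) and each return level (0/50/75/100), the
#' percentage of "trust" decisions among interactions in which the subject
#' returned that amount. Levels with no observations are absent, not zero.
#'
#' @param interactions validated interaction table.
#' @return data.frame with columns `sex`, `partner_class`, `return_level`,
#'   `n`, `pct_trust`.
#' @export
associationCurve <- function(interactions) {
  interactions <- validateInteractions(interactions)
  pclass <- ifelse(is.na(interactions$partner_id), "anon",
                   as.character(interactions$partner_sex))
  rows <- list()
  for (sx in unique(interactions$subject_sex))
    for (pc in unique(pclass))
      for (lev in RETURN_LEVELS) {
        sel <- interactions$subject_sex == sx & pclass == pc &
          interactions$return_amount == lev
        if (any(sel))
          rows[[length(rows) + 1]] <- data.frame(
            sex = sx, partner_class = pc, return_level = lev, n = sum(sel),
            pct_trust = 100 * mean(interactions$trust_decision[sel]))
      }
  out <- do.call(rbind, rows)
  out[order(out$sex, out$partner_class, out$return_level), ]
}

#' Per-interaction switch and shift records
#'
#' For every personalized interaction, the change relative to the
#' subject's anonymous baseline: `trust_switch` is +1 for a switch from
#' distrust (anonymous) to trust (personalized), -1 for the reverse, 0
#' when the decisions agree; `return_shift` is the signed difference in
#' returned points (personalized minus anonymous); `zero_return_change`
#' flags gaining (+1) or losing (-1) a zero return.
#'
#' @param interactions validated interaction table; every subject with
#'   personalized records must have an anonymous record.
#' @return data.frame with columns `subject_id`, `subject_sex`,
#'   `partner_id`, `partner_sex`, `setting`, `trust_switch`,
#'   `return_shift`, `zero_return_change`.
#' @export
shiftRecords <- function(interactions) {
  interactions <- validateInteractions(interactions)
  anon <- .anonTable(interactions)
  rownames(anon) <- anon$subject_id
  pers <- interactions[!is.na(interactions$partner_id), ]
  missing <- setdiff(unique(pers$subject_id), anon$subject_id)
  if (length(missing))
    stop("subjects without an anonymous baseline: ",
         paste(missing, collapse = ", "))
  base <- anon[as.character(pers$subject_id), ]
  data.frame(subject_id = pers$subject_id, subject_sex = pers$subject_sex,
             partner_id = pers$partner_id, partner_sex = pers$partner_sex,
             setting = pers$setting,
             trust_switch = as.integer(pers$trust_decision) -
               as.integer(base$trust_decision),
             return_shift = pers$return_amount - base$return_amount,
             zero_return_change = as.integer(pers$return_amount == 0) -
               as.integer(base$return_amount == 0))
}

#' Per-stimulus (video) shift summaries
#'
#' For each stimulus partner and each rater sex: the shift in trust
#' frequency (personalized trust frequency minus anonymous trust frequency
#' over that video's raters, i.e. the mean trust switch), the mean signed
#' return shift, and the shift in zero-return frequency. Cells with no
#' raters of a sex are absent.
#'
#' @param shifts data.frame from [shiftRecords()].
#' @return data.frame with columns `partner_id`, `partner_sex`,
#'   `rater_sex`, `n_raters`, `trust_shift`, `return_shift`,
#'   `zero_return_shift`.
#' @export
videoShiftSummary <- function(shifts) {
  rows <- list()
  for (pid in unique(shifts$partner_id))
    for (sx in unique(shifts$subject_sex)) {
      sel <- shifts$partner_id == pid & shifts$subject_sex == sx
      if (!any(sel)) next
      rows[[length(rows) + 1]] <- data.frame(
        partner_id = pid, partner_sex = shifts$partner_sex[sel][1],
        rater_sex = sx, n_raters = sum(sel),
        trust_shift = mean(shifts$trust_switch[sel]),
        return_shift = mean(shifts$return_shift[sel]),
        zero_return_shift = mean(shifts$zero_return_change[sel]))
    }
  out <- do.call(rbind, rows)
  out[order(out$partner_id, out$rater_sex), ]
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Chance-corrected agreement across `n` ratings per item:
#' `kappa = (Pbar - Pe) / (1 - Pe)` with `Pbar` the mean observed pairwise
#' agreement per item and `Pe` the expected agreement from the marginal
#' category frequencies. Here items are subjects and the ratings are their
#' five Trust-Game decisions, treated as interchangeable expressions of
#' one behavioral disposition. Significance against kappa = 0 uses the
#' large-sample normal approximation of Fleiss (1971).
#'
#' @param ratings matrix or data.frame, items x ratings (equal number of
#'   non-missing ratings per item, at least 2).
#' @param categories optional category labels; defaults to the observed
#'   values.
#' @return a [KappaResult-class]. When every rating falls in one category
#'   (`Pe = 1`) kappa is undefined and the result is flagged.
#' @examples
#' fleissKappa(matrix(rep(c(1, 1, 1, 0, 0), 4), 4, 5, byrow = TRUE))
#' @export
fleissKappa <- function(ratings, categories = NULL) {
  ratings <- as.matrix(ratings)
  N <- nrow(ratings); n <- ncol(ratings)
  if (any(is.na(ratings))) stop("ratings must be complete")
  if (n < 2) stop("need at least 2 ratings per item")
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  counts <- t(apply(ratings, 1, function(row)
    tabulate(factor(row, levels = categories), nbins = length(categories))))
  if (length(categories) == 1) counts <- matrix(n, N, 1)
  pj <- colSums(counts) / (N * n)
  Pe <- sum(pj^2)
  if (Pe >= 1 - 1e-12)
    return(new("KappaResult", kappa = NA_real_, z = NA_real_, p = NA_real_,
               nItems = as.integer(N), nRatings = as.integer(n),
               categories = as.character(categories), flagged = TRUE))
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  kappa <- (Pbar - Pe) / (1 - Pe)
  seNull <- sqrt(2 / (N * n * (n - 1))) *
    sqrt(Pe - (2 * n - 3) * Pe^2 + 2 * (n - 2) * sum(pj^3)) / (1 - Pe)
  z <- kappa / seNull
  p <- 2 * stats::pnorm(-abs(z))
  new("KappaResult", kappa = kappa, z = z, p = p, nItems = as.integer(N),
      nRatings = as.integer(n), categories = as.character(categories),
      flagged = FALSE)
}

#' Decision ratings matrices for consistency analysis
#'
#' Builds the items x ratings matrices fed to [fleissKappa()]: one row per
#' subject with complete decisions in all five settings; `trust` ratings
#' are the five binary trust decisions, `fairness` ratings binarize the
#' five returns as fair (100 points) versus non-fair (0/50/75).
#'
#' @param interactions validated interaction table.
#' @return list with matrices `trust` and `fairness` (subjects x 5).
#' @export
decisionRatings <- function(interactions) {
  interactions <- validateInteractions(interactions)
  settings <- c("anon", "SS1", "SS2", "OS1", "OS2")
  wideT <- wideR <- NULL
  ids <- unique(interactions$subject_id)
  rows <- lapply(ids, function(id) {
    sub <- interactions[interactions$subject_id == id, ]
    if (!all(settings %in% sub$setting)) return(NULL)
    sub <- sub[match(settings, sub$setting), ]
    list(trust = as.integer(sub$trust_decision),
         fair = as.integer(sub$return_amount == 100))
  })
  keep <- !vapply(rows, is.null, TRUE)
  list(trust = do.call(rbind, lapply(rows[keep], `[[`, "trust")),
       fairness = do.call(rbind, lapply(rows[keep], `[[`, "fair")))
}
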