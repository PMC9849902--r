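test_that("payoff settlement follows the game rules and conserves points", {
  expect_equal(settlePayoffs(FALSE, NA), data.frame(trustor = 50,
                                                    trustee = 0))
  expect_equal(settlePayoffs(TRUE, 100), data.frame(trustor = 100,
                                                    trustee = 50))
  expect_equal(settlePayoffs(TRUE, 0), data.frame(trustor = 0,
                                                  trustee = 150))
  expect_error(settlePayoffs(TRUE, 60), "invalid return")
  # conservation: 150 when entrusted, 50 otherwise
  set.seed(71)
  ent <- runif(50) < 0.5
  ret <- sample(c(0, 50, 75, 100), 50, replace = TRUE)
  pay <- settlePayoffs(ent, ret)
  expect_equal(pay$trustor + pay$trustee, ifelse(ent, 150, 50))
})

test_that("payoff matching settles against partners' anonymous decisions", {
  ia <- toyInteractions()
  # make the video partners real subjects with anonymous decisions
  partners <- do.call(rbind, lapply(
    c("p_ss1", "p_ss2", "p_os1", "p_os2"), function(p)
      data.frame(subject_id = p, subject_sex = "male",
                 partner_id = NA_character_, setting = "anon",
                 partner_sex = NA_character_, acquainted = FALSE,
                 trust_decision = TRUE, return_amount = 75,
                 stringsAsFactors = FALSE)))
  full <- rbind(ia, partners)
  out <- matchPayoffs(full, seed = 3)
  s <- out$settled
  # entrusting subject receives the partner's anonymous return (75)
  expect_true(all(s$trustor_payoff[!is.na(s$partner_id) &
                                     s$trust_decision] == 75))
  # keeping yields 50 regardless of the partner
  expect_true(all(s$trustor_payoff[!s$trust_decision] == 50))
  # deterministic given the seed
  out2 <- matchPayoffs(full, seed = 3)
  expect_identical(out$totals, out2$totals)
  expect_error(matchPayoffs(ia, seed = 1), "p_ss1")
})

test_that("acquaintance exclusion removes flagged rows and is idempotent", {
  ia <- toyInteractions()
  ia$acquainted[c(2, 9)] <- TRUE
  out <- excludeAcquainted(ia)
  expect_equal(out$nRemoved, 2L)
  expect_equal(nrow(out$interactions), 13L)
  again <- excludeAcquainted(out$interactions)
  expect_equal(again$nRemoved, 0L)
  expect_identical(again$interactions, out$interactions)
})

test_that("rate summaries and association curves handle constructed populations", {
  ia <- toyInteractions()
  ia$trust_decision <- TRUE
  rates <- summarizeRates(ia)
  expect_true(all(rates$pct_trust == 100))
  # only 100-returners trust: step association curve
  ia2 <- toyInteractions()
  ia2$trust_decision <- ia2$return_amount == 100
  curve <- associationCurve(ia2)
  expect_true(all(curve$pct_trust[curve$return_level == 100] == 100))
  expect_true(all(curve$pct_trust[curve$return_level < 100] == 0))
  # empty levels are absent, not zero
  expect_false(any(curve$n == 0))
  # simulated Bernoulli(0.6) trust rate is recovered within a binomial CI
  b <- generateBehavior(behaviorSimConfig(seed = 72, thetaSd = 0,
    alphaTrust = qlogis(0.6), betaPersonal = 0, betaPartnerSex = 0,
    betaFem = 0, betaFemByDmSex = 0))
  r <- summarizeRates(b$interactions)
  pooled <- r[r$sex == "all", ]
  expect_lt(abs(pooled$pct_trust / 100 - 0.6),
            3 * sqrt(0.6 * 0.4 / pooled$n))
})

test_that("shift records encode switches and signed return shifts", {
  ia <- toyInteractions()
  sh <- shiftRecords(ia)
  expect_equal(nrow(sh), 12L)
  s1 <- sh[sh$subject_id == "s1", ]
  expect_equal(s1$trust_switch, c(1, 0, 0, 0))   # distrust -> trust once
  expect_equal(s1$return_shift, c(25, 0, 0, 0))  # 75 - 50
  s2 <- sh[sh$subject_id == "s2", ]
  expect_equal(sum(s2$trust_switch == -1), 1L)
  expect_equal(s2$return_shift, c(0, 0, -100, 0))
  expect_equal(s2$zero_return_change, c(0, 0, 1, 0))
  expect_true(all(sh$trust_switch[sh$subject_id == "s3"] == 0))
  # identical decisions everywhere: all-zero shifts
  ia0 <- toyInteractions()
  ia0$trust_decision <- TRUE; ia0$return_amount <- 75
  expect_true(all(shiftRecords(ia0)$trust_switch == 0))
  expect_true(all(shiftRecords(ia0)$return_shift == 0))
  expect_error(shiftRecords(ia[ia$setting != "anon", ]), "baseline")
})

test_that("per-video summaries average the raters' shifts", {
  # 4 raters of one video: 2 switch to trust, 2 unchanged -> shift +0.5
  mk <- function(sid, anonTrust, persTrust)
    data.frame(subject_id = sid, subject_sex = "female",
               partner_id = c(NA, "v1"), setting = c("anon", "SS1"),
               partner_sex = c(NA, "female"), acquainted = FALSE,
               trust_decision = c(anonTrust, persTrust),
               return_amount = 50, stringsAsFactors = FALSE)
  ia <- rbind(mk("a", FALSE, TRUE), mk("b", FALSE, TRUE),
              mk("c", TRUE, TRUE), mk("d", FALSE, FALSE))
  vs <- videoShiftSummary(shiftRecords(ia))
  expect_equal(vs$trust_shift, 0.5)
  expect_equal(vs$n_raters, 4L)
  expect_equal(vs$return_shift, 0)
})

test_that("switch aggregation is internally consistent with the rate summaries", {
  b <- generateBehavior(behaviorSimConfig(seed = 73))
  ia <- b$interactions
  sh <- shiftRecords(ia)
  rates <- summarizeRates(ia)
  # every subject contributes 1 anonymous and 4 personalized decisions, so
  # the mean trust switch equals the personalized-minus-anonymous trust
  # frequency difference exactly
  anonPct <- sum(rates$pct_trust[rates$setting == "Anon"] *
                   rates$n[rates$setting == "Anon"]) /
    sum(rates$n[rates$setting == "Anon"])
  persSel <- rates$setting %in% c("Pers SS", "Pers OS")
  persPct <- sum(rates$pct_trust[persSel] * rates$n[persSel]) /
    sum(rates$n[persSel])
  expect_equal(mean(sh$trust_switch), (persPct - anonPct) / 100,
               tolerance = 1e-12)
})

test_that("Fleiss' kappa matches its definition and known endpoints", {
  # perfectly consistent subjects (with between-subject variation) -> 1
  perfect <- rbind(matrix(1, 10, 5), matrix(0, 7, 5))
  expect_equal(fleissKappa(perfect)@kappa, 1)
  # all ratings in a single category -> undefined, flagged
  expect_true(fleissKappa(matrix(1, 10, 5))@flagged)
  # independent uniform ratings, 500 items -> kappa near 0
  set.seed(74)
  rnd <- matrix(sample(0:3, 500 * 5, replace = TRUE), 500, 5)
  expect_lt(abs(fleissKappa(rnd)@kappa), 0.05)
  # direct-formula oracle on random tables
  for (s in 1:5) {
    set.seed(s)
    r <- matrix(sample(1:3, 40 * 4, replace = TRUE), 40, 4)
    k <- fleissKappa(r)
    counts <- t(apply(r, 1, tabulate, nbins = 3))
    pj <- colSums(counts) / sum(counts)
    Pbar <- mean((rowSums(counts^2) - 4) / (4 * 3))
    Pe <- sum(pj^2)
    expect_equal(k@kappa, (Pbar - Pe) / (1 - Pe), tolerance = 1e-12)
  }
  # invariance under category relabeling and rating-order permutation
  set.seed(75)
  r <- matrix(sample(0:1, 30 * 5, replace = TRUE), 30, 5)
  k0 <- fleissKappa(r)@kappa
  expect_equal(fleissKappa(1 - r)@kappa, k0)
  expect_equal(fleissKappa(t(apply(r, 1, sample)))@kappa, k0)
})

test_that("decision ratings use complete cases and binarize fairness", {
  ia <- toyInteractions()
  r <- decisionRatings(ia)
  expect_equal(dim(r$trust), c(3L, 5L))
  expect_equal(r$fairness[2, ], c(1, 1, 1, 0, 1))
  # a subject lacking a setting is dropped
  r2 <- decisionRatings(ia[-1, ])
  expect_equal(nrow(r2$trust), 2L)
})
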