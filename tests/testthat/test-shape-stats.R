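test_that("permutation MANOVA agrees exactly with an exhaustive oracle", {
  set.seed(61)
  y <- matrix(rnorm(18), 6, 3)
  g <- rep(c("a", "b"), each = 3)
  pm <- allPerms(6)
  res <- permutationManova(y, data.frame(group = g), permutations = pm)
  oracle <- centroidF(y, g)
  expect_equal(unname(res@varianceExplained["group"]),
               oracle$ssb / oracle$sst, tolerance = 1e-10)
  expect_equal(unname(res@pseudoF["group"]), oracle$f, tolerance = 1e-10)
  # p from exhaustive relabeling, computed independently from centroids
  fstar <- apply(pm, 1, function(p) centroidF(y, g[order(p)])$f)
  # permuting responses by p is relabeling by the inverse permutation
  expect_equal(unname(res@pPerm["group"]),
               mean(fstar >= oracle$f - 1e-12), tolerance = 1e-12)
})

test_that("sequential decomposition matches vegan::adonis2 term by term", {
  skip_if_not_installed("vegan")
  set.seed(62)
  y <- matrix(rnorm(48), 12, 4)
  fac <- data.frame(age = rnorm(12), sex = rep(c("m", "f"), 6))
  res <- permutationManova(y, fac, nPerm = 99, seed = 1)
  ad <- vegan::adonis2(dist(y) ~ age + sex, data = fac, by = "terms",
                       permutations = 99)
  expect_equal(unname(res@ss[c("age", "sex", "Residual")]),
               ad$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(unname(res@pseudoF[c("age", "sex")]), ad$F[1:2],
               tolerance = 1e-8)
  expect_equal(unname(res@varianceExplained), ad$R2[1:2],
               tolerance = 1e-8)
  # variance fractions plus the residual fraction sum to one
  expect_equal(sum(res@ss), sum(diag(FaceTrust:::.gowerG(y))),
               tolerance = 1e-10)
})

test_that("degenerate and null MANOVA inputs are handled", {
  y <- matrix(1, 8, 3)
  res <- permutationManova(y, data.frame(g = rep(c("a", "b"), 4)),
                           nPerm = 19)
  expect_true(res@flagged)
  expect_true(all(is.na(res@pPerm)))
  # two groups given identical duplicated coordinate sets: zero
  # between-group variance
  set.seed(63)
  half <- matrix(rnorm(12), 4, 3)
  res2 <- permutationManova(rbind(half, half),
                            data.frame(g = rep(c("a", "b"), each = 4)),
                            nPerm = 19, seed = 1)
  expect_equal(unname(res2@varianceExplained["g"]), 0, tolerance = 1e-10)
})

test_that("repeatability is 1 on identical replicates and falls to 0 under pure noise", {
  set.seed(64)
  means <- matrix(rnorm(30 * 4, sd = 1), 30, 4)
  exact <- means[rep(1:30, each = 2), ]
  expect_equal(repeatability(exact, rep(1:30, each = 2)), 1)
  noise <- matrix(rnorm(100 * 2 * 4), 200, 4)
  expect_lt(repeatability(noise, rep(1:100, each = 2)), 0.1)
  # monotone in signal-to-noise
  r <- vapply(c(0.2, 1, 5), function(s) {
    sig <- matrix(rnorm(40 * 4, sd = s), 40, 4)[rep(1:40, each = 2), ] +
      matrix(rnorm(80 * 4, sd = 0.5), 80, 4)
    repeatability(sig, rep(1:40, each = 2))
  }, 0)
  expect_true(all(diff(r) > 0))
  expect_error(repeatability(means, 1:30), "2 replicates")
})

test_that("repeatability is invariant to relabeling and to similarity transforms", {
  faces <- generateFaces(faceSimConfig(nMale = 8, nFemale = 8,
                                       nObservers = 2, seed = 65))
  al <- gpa(faces)
  r1 <- repeatability(al)
  ids <- sampleInfo(al)$individual_id
  relab <- setNames(sample(unique(ids)), unique(ids))
  expect_equal(repeatability(flattenShapes(al), relab[ids]), r1)
  # global similarity transform of every raw shape before GPA
  co <- shapeCoords(faces)
  th <- 0.8; R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  co2 <- co
  for (i in seq_len(dim(co)[1]))
    co2[i, , ] <- 3 * co[i, , ] %*% R + 5
  faces2 <- ShapeSet(lapply(seq_len(dim(co2)[1]), function(i) co2[i, , ]),
                     info = sampleInfo(faces), scheme = landmarkScheme(faces))
  expect_equal(repeatability(gpa(faces2)), r1, tolerance = 1e-6)
})

test_that("discriminant femininity scores separate, flip and rotate correctly", {
  set.seed(66)
  n <- 40
  X <- rbind(matrix(rnorm(n * 6), n, 6), matrix(rnorm(n * 6), n, 6))
  X[(n + 1):(2 * n), 1] <- X[(n + 1):(2 * n), 1] + 10
  sex <- rep(c("male", "female"), each = n)
  sc <- ldaFemininity(X, sex)
  tab <- femininityTable(sc)
  # well-separated clouds: the score sign classifies perfectly
  thr <- mean(c(max(tab$raw_score[tab$sex == "male"]),
                min(tab$raw_score[tab$sex == "female"])))
  expect_true(all(tab$raw_score[tab$sex == "female"] > thr))
  expect_true(all(tab$raw_score[tab$sex == "male"] < thr))
  # swapping the labels negates the raw scores (orientation re-applied)
  sc2 <- ldaFemininity(X, ifelse(sex == "male", "female", "male"))
  expect_equal(femininityTable(sc2)$raw_score, -tab$raw_score,
               tolerance = 1e-8)
  # invariant (up to sign) to a common orthogonal rotation of coordinates
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  sc3 <- ldaFemininity(X %*% Q, sex)
  expect_equal(abs(cor(femininityTable(sc3)$raw_score, tab$raw_score)), 1,
               tolerance = 1e-6)
  expect_error(ldaFemininity(X, rep("male", 2 * n)), "both sexes")
})

test_that("femininity scores agree with MASS::lda up to scale", {
  skip_if_not_installed("MASS")
  set.seed(67)
  X <- matrix(rnorm(60 * 4), 60, 4)
  sex <- rep(c("male", "female"), 30)
  X[sex == "female", 2] <- X[sex == "female", 2] + 1.5
  sc <- ldaFemininity(X, sex, varianceCap = 1, maxComponents = 4)
  ld <- MASS::lda(X, grouping = sex)
  proj <- as.numeric(scale(X, center = TRUE, scale = FALSE) %*%
                       ld$scaling)
  expect_equal(abs(cor(femininityTable(sc)$raw_score, proj)), 1,
               tolerance = 1e-8)
})

test_that("z-standardization hits mean 0 / SD 1 in both contexts and is idempotent", {
  set.seed(68)
  al <- gpa(generateFaces(faceSimConfig(nMale = 15, nFemale = 15,
                                        seed = 68)))
  sc <- ldaFemininity(al)
  tab <- femininityTable(sc)
  for (g in c("male", "female")) {
    expect_equal(mean(tab$z_full[tab$sex == g]), 0, tolerance = 1e-10)
    expect_equal(sd(tab$z_full[tab$sex == g]), 1, tolerance = 1e-10)
  }
  expect_equal(femininityTable(zStandardize(sc)), tab)
  # subsample standardization on a 4-member toy subset, checked by hand
  sub <- c("m001", "m002", "f001", "f002")
  sc2 <- zStandardize(sc, subset = sub)
  t2 <- femininityTable(sc2)
  for (g in c("male", "female")) {
    raw <- tab$raw_score[tab$individual_id %in% sub & tab$sex == g]
    hand <- (raw - mean(raw)) / sd(raw)
    expect_equal(t2$z_partner[t2$individual_id %in% sub & t2$sex == g],
                 hand)
  }
  expect_true(all(is.na(t2$z_partner[!t2$individual_id %in% sub])))
  # the two standardizations differ for the same individuals
  expect_false(isTRUE(all.equal(
    t2$z_partner[t2$individual_id %in% sub],
    t2$z_full[t2$individual_id %in% sub])))
})

test_that("null permutation p-values are uniform within Monte-Carlo error", {
  set.seed(69)
  pvals <- replicate(300, {
    y <- matrix(rnorm(20 * 3), 20, 3)
    permutationManova(y, data.frame(g = rep(c("a", "b"), each = 10)),
                      nPerm = 99, seed = sample.int(1e6, 1))@pPerm
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
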