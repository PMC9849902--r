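# Shared fixtures and independent oracles used across test files.

# all permutations of 1:n (n small), one per row
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# classical one-factor MANOVA decomposition computed directly from group
# centroids (independent of the distance-matrix implementation)
centroidF <- function(y, g) {
  g <- factor(g)
  n <- nrow(y); k <- nlevels(g)
  grand <- colMeans(y)
  ssb <- sum(vapply(levels(g), function(l) {
    sel <- g == l
    sum(sel) * sum((colMeans(y[sel, , drop = FALSE]) - grand)^2)
  }, 0))
  sst <- sum(sweep(y, 2, grand)^2)
  ssw <- sst - ssb
  list(ssb = ssb, sst = sst,
       f = (ssb / (k - 1)) / (ssw / (n - k)))
}

# independently coded TPS bending-energy matrix (own kernel inversion)
oracleBendingMatrix <- function(pts) {
  p <- nrow(pts)
  K <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    r2 <- sum((pts[i, ] - pts[j, ])^2)
    K[i, j] <- if (r2 > 0) r2 * log(sqrt(r2)) else 0
  }
  P <- cbind(1, pts)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  solve(L)[1:p, 1:p]
}

# a small deterministic interaction table: 3 subjects x 5 settings
toyInteractions <- function() {
  mk <- function(sid, ssex, trust, ret) {
    partners <- c(NA, "p_ss1", "p_ss2", "p_os1", "p_os2")
    psex <- c(NA, ssex, ssex, setdiff(c("male", "female"), ssex),
              setdiff(c("male", "female"), ssex))
    data.frame(subject_id = sid, subject_sex = ssex,
               partner_id = partners,
               setting = c("anon", "SS1", "SS2", "OS1", "OS2"),
               partner_sex = psex, acquainted = FALSE,
               trust_decision = trust, return_amount = ret,
               stringsAsFactors = FALSE)
  }
  rbind(mk("s1", "male",   c(FALSE, TRUE, FALSE, FALSE, FALSE),
        c(50, 75, 50, 50, 50)),                      # one switch to trust
        mk("s2", "female", c(TRUE, FALSE, TRUE, TRUE, TRUE),
        c(100, 100, 100, 0, 100)),                   # one switch to distrust
        mk("s3", "male",   c(TRUE, TRUE, TRUE, TRUE, TRUE),
        c(0, 0, 0, 0, 0)))                           # no switches
}

# random shapes around a base pentagon
randomShapes <- function(n, p = 5, noise = 0.05, seed = 1) {
  set.seed(seed)
  base <- cbind(cos(2 * pi * (1:p) / p), sin(2 * pi * (1:p) / p))
  lapply(seq_len(n), function(i)
    base + matrix(rnorm(2 * p, sd = noise), p, 2))
}
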