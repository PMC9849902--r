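#' Generalized estimating equations with robust variance
#'
#' Marginal regression for repeated-measures data: binary logistic or
#' linear models estimated by GEE with an exchangeable (default) or
#' independence working correlation within clusters, and robust
#' (sandwich) standard errors. Each coefficient is tested with a Wald
#' chi-squared statistic `(B / robust SE)^2` on 1 df. Because robust
#' standard errors are always reported, the working-correlation choice is
#' second order for inference.
#'
#' @param formula model formula (interactions allowed).
#' @param data data.frame.
#' @param id cluster (subject) identifier: a vector or the name of a
#'   column of `data`.
#' @param family "binomial" (logit link) or "gaussian" (identity).
#' @param corstr "exchangeable" or "independence".
#' @param tol convergence tolerance on the coefficient change
#'   (default 1e-8).
#' @param maxIter iteration cap (default 100).
#' @return a [GEEResult-class].
#' @examples
#' d <- data.frame(y = rbinom(40, 1, 0.5), x = rnorm(40),
#'                 id = rep(1:10, each = 4))
#' geeFit(y ~ x, d, id = "id", family = "binomial")
#' @export
geeFit <- function(formula, data, id, family = c("binomial", "gaussian"),
                   corstr = c("exchangeable", "independence"),
                   tol = 1e-8, maxIter = 100L) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  if (is.character(id) && length(id) == 1) id <- data[[id]]
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  id <- factor(id[keep])
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  N <- length(y); p <- ncol(X)
  clusters <- split(seq_len(N), id)
  K <- length(clusters)
  if (K < 2) stop("GEE requires at least 2 clusters")
  if (family == "binomial") {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("binomial family needs a binary outcome")
    linkinv <- stats::plogis
    varfun <- function(mu) mu * (1 - mu)
    mueta <- function(eta) { m <- stats::plogis(eta); m * (1 - m) }
  } else {
    linkinv <- identity
    varfun <- function(mu) rep(1, length(mu))
    mueta <- function(eta) rep(1, length(eta))
  }
  beta <- stats::coef(stats::glm.fit(X, y,
    family = if (family == "binomial") stats::binomial() else stats::gaussian()))
  beta[!is.finite(beta)] <- 0
  npairs <- sum(vapply(clusters, function(ix) {
    n <- length(ix); n * (n - 1) / 2 }, 0))
  alpha <- 0
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    eta <- drop(X %*% beta)
    if (family == "binomial" && max(abs(eta)) > 30) {
      worst <- names(beta)[which.max(abs(beta))]
      stop("non-convergence consistent with separation (fitted ",
           "probabilities at 0/1); check predictor '", worst, "'")
    }
    mu <- linkinv(eta)
    v <- varfun(mu)
    res <- y - mu
    e <- res / sqrt(v)
    phi <- sum(e^2) / (N - p)
    if (corstr == "exchangeable" && npairs > p) {
      num <- sum(vapply(clusters, function(ix) {
        ei <- e[ix]; (sum(ei)^2 - sum(ei^2)) / 2 }, 0))
      alpha <- num / (phi * (npairs - p))
      nmax <- max(vapply(clusters, length, 1L))
      # cap below 1: responses that are constant within clusters would
      # otherwise drive the working correlation singular
      alpha <- min(max(alpha, -1 / (nmax - 1) + 1e-6), 0.95)
    }
    M <- matrix(0, p, p); U <- numeric(p)
    meat <- matrix(0, p, p)
    for (ix in clusters) {
      ni <- length(ix)
      Di <- X[ix, , drop = FALSE] * mueta(eta[ix])
      Ah <- sqrt(v[ix])
      # exchangeable inverse in closed form
      if (ni == 1 || alpha == 0) {
        Vinv_r <- res[ix] / (phi * v[ix])
        Vinv_D <- Di / (phi * v[ix])
      } else {
        r_std <- res[ix] / Ah
        D_std <- Di / Ah
        f <- alpha / (1 + (ni - 1) * alpha)
        Rinvr <- (r_std - f * sum(r_std)) / (1 - alpha)
        RinvD <- (D_std - matrix(f * colSums(D_std), ni, p,
                                 byrow = TRUE)) / (1 - alpha)
        Vinv_r <- Rinvr / (phi * Ah)
        Vinv_D <- RinvD / (phi * Ah)
      }
      M <- M + crossprod(Di, Vinv_D)
      ui <- crossprod(Di, Vinv_r)
      U <- U + ui
      meat <- meat + tcrossprod(ui)
    }
    step <- tryCatch(solve(M, U), error = function(e)
      stop("singular GEE working model; drop collinear predictors"))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    if (it >= maxIter) break
  }
  Minv <- solve(M)
  vcovR <- Minv %*% meat %*% Minv
  se <- sqrt(diag(vcovR))
  names(beta) <- names(se) <- colnames(X)
  wald <- (beta / se)^2
  new("GEEResult", coefficients = beta, robustSE = se, waldX2 = wald,
      p = stats::pchisq(wald, 1, lower.tail = FALSE), family = family,
      workingCorrelation = corstr, alpha = alpha,
      nClusters = as.integer(K), nObs = as.integer(N),
      nIterations = it, converged = converged)
}
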