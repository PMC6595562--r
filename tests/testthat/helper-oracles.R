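# Independent oracles used to verify the package's estimators.

# Monte-Carlo gene-dropping estimate of the additive relationship matrix:
# founders get unique allele labels, alleles drop through the pedigree, and
# a_ij is estimated as 2 * kinship(i, j) from allele identity by descent.
geneDropA <- function(pedigree, nRep = 20000, seed = 1) {
  n <- nrow(pedigree)
  s <- match(pedigree$sire, pedigree$id)
  d <- match(pedigree$dam, pedigree$id)
  acc <- matrix(0, n, n)
  withr::with_seed(seed, {
    for (r in seq_len(nRep)) {
      h1 <- integer(n); h2 <- integer(n)
      lab <- 0L
      for (i in seq_len(n)) {
        if (is.na(s[i])) h1[i] <- (lab <- lab + 1L)
        else h1[i] <- if (stats::runif(1) < 0.5) h1[s[i]] else h2[s[i]]
        if (is.na(d[i])) h2[i] <- (lab <- lab + 1L)
        else h2[i] <- if (stats::runif(1) < 0.5) h1[d[i]] else h2[d[i]]
      }
      # kinship f_ij = P(random allele from i IBD to random allele from j)
      f <- (outer(h1, h1, "==") + outer(h1, h2, "==") +
              outer(h2, h1, "==") + outer(h2, h2, "==")) / 4
      acc <- acc + 2 * f
    }
  })
  # a_ii from gene dropping is 2*f_ii = 1 + P(two alleles of i IBD)
  acc / nRep
}

# Brute-force GLS single-marker association with an explicit covariance
# inverse (the fast-mode oracle).
glsGwasOracle <- function(y, W, A, sigmaA, sigmaE) {
  n <- length(y)
  V <- sigmaA * A + sigmaE * diag(n)
  Vi <- solve(V)
  t(vapply(seq_len(ncol(W)), function(j) {
    X <- cbind(1, W[, j])
    XtViX <- t(X) %*% Vi %*% X
    b <- solve(XtViX, t(X) %*% Vi %*% y)
    se <- sqrt(solve(XtViX)[2, 2])
    c(beta = b[2], se = se,
      p = stats::pchisq((b[2] / se)^2, 1, lower.tail = FALSE))
  }, numeric(3)))
}

# Henderson's mixed-model equations for a pedigree BLUP with all-animal
# incidence; returns breeding values for every animal (trained on records
# with non-missing y).
mmeBlupOracle <- function(y, A, sigmaA, sigmaE) {
  n <- length(y)
  obs <- !is.na(y)
  X <- matrix(1, sum(obs), 1)
  Z <- diag(n)[obs, , drop = FALSE]
  Ai <- solve(A)
  lam <- sigmaE / sigmaA
  lhs <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + Ai * lam))
  rhs <- c(crossprod(X, y[obs]), crossprod(Z, y[obs]))
  sol <- solve(lhs, rhs)
  list(beta = sol[1], u = sol[-1])
}

# dense-formula restricted log-likelihood, written independently of the
# package's internals (used for grid-search checks)
denseRemlLoglik <- function(y, X, Ks, sigma2) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(sigma2[length(sigma2)], n)
  for (i in seq_along(Ks)) V <- V + sigma2[i] * Ks[[i]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  -0.5 * ((n - p) * log(2 * pi) + determinant(V)$modulus +
            determinant(XtViX)$modulus + t(r) %*% Vi %*% r)[1]
}
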