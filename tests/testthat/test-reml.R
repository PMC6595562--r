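# REML engine, BLUP solver and the boundary-mixture likelihood-ratio test.

test_that("the mixture LRT p-value has its closed forms", {
  expect_equal(lrtMixtureP(0, 0)$p, 0.5)
  l95 <- qchisq(0.95, 1)
  expect_equal(lrtMixtureP(l95 / 2, 0)$p, 0.025, tolerance = 1e-6)
  # -log10(p) = 3 is attained at the 1 - 0.002 chi-square quantile
  l <- qchisq(1 - 0.002, 1)
  expect_equal(-log10(lrtMixtureP(l / 2, 0)$p), 3, tolerance = 1e-9)
  # an optimizer deficit beyond tolerance is clamped with a warning
  expect_warning(out <- lrtMixtureP(-1, 0), "clamped")
  expect_equal(out$lrt, 0)
})

test_that("REML estimates scale as variances under response rescaling", {
  pop <- tinyPop()
  y <- pop$ystar$ystar
  f1 <- remlFit(y, K = list(a = pop$A), computeSe = FALSE)
  f2 <- remlFit(3 * y, K = list(a = pop$A), computeSe = FALSE)
  expect_equal(f2$sigma2, 9 * f1$sigma2, tolerance = 1e-4)
})

test_that("the fitted restricted likelihood dominates a parameter grid", {
  set.seed(14)
  n <- 200
  Z <- matrix(rbinom(n * 80, 2, 0.5), n, 80)
  K <- tcrossprod(scale(Z)) / 80
  u <- drop(chol(K + diag(1e-6, n)) %*% rnorm(n)) * sqrt(0.5)
  y <- u + rnorm(n, 0, sqrt(0.5))
  fit <- remlFit(y, K = list(g = K), computeSe = FALSE)
  X <- matrix(1, n, 1)
  grid <- expand.grid(s1 = seq(0.05, 1.4, length.out = 10),
                      s2 = seq(0.05, 1.4, length.out = 10))
  lls <- mapply(function(a, b) denseRemlLoglik(y, X, list(K), c(a, b)),
                grid$s1, grid$s2)
  expect_gte(fit$loglik + 1e-6, max(lls))
  # the package loglik matches the independent dense formula at the optimum
  expect_equal(fit$loglik,
               denseRemlLoglik(y, X, list(K), unname(fit$sigma2)),
               tolerance = 1e-6)
})

test_that("an identity kernel is flagged as non-identifiable", {
  set.seed(15)
  y <- rnorm(60)
  expect_warning(remlFit(y, K = list(I = diag(60)), computeSe = FALSE),
                 "identifiable")
})

test_that("REML matches the ANOVA estimator on balanced half-sib data", {
  set.seed(16)
  s <- 60; k <- 12
  sire <- factor(rep(seq_len(s), each = k))
  u <- rnorm(s, 0, sqrt(0.12))
  y <- u[sire] + rnorm(s * k, 0, sqrt(0.88))
  Z <- outer(sire, levels(sire), "==") + 0
  fit <- remlFit(y, K = list(sire = tcrossprod(Z)), computeSe = FALSE)
  av <- anova(lm(y ~ sire))
  s2anova <- (av$`Mean Sq`[1] - av$`Mean Sq`[2]) / k
  expect_equal(fit$sigma2[["sire"]], s2anova, tolerance = 0.01)
  expect_equal(fit$sigma2[["residual"]], av$`Mean Sq`[2], tolerance = 0.02)
})

test_that("all solver routes maximise the same restricted likelihood", {
  pop <- tinyPop()
  ids <- pop$final$id
  y <- pop$ystar$ystar
  mk <- markerMap(pop$genotypes)
  G <- regionalGrm(pop$genotypes, 1, 1, 2e6, samples = ids, minVariants = 5)
  wood <- remlFit(y, K = list(a = pop$A, reg = list(Z = G@factor)),
                  computeSe = FALSE)
  dens <- remlFit(y, K = list(a = relMatrix(pop$A), reg = relMatrix(G)),
                  computeSe = FALSE)
  expect_equal(wood$method, "woodbury")
  expect_equal(dens$method, "ai")
  expect_equal(wood$loglik, dens$loglik, tolerance = 1e-3)
  expect_equal(wood$sigma2, dens$sigma2, tolerance = 0.02)
})

test_that("variance recovery is unbiased for a GRM-structured trait", {
  set.seed(17)
  n <- 500
  Z <- matrix(rbinom(n * 300, 2, runif(300, 0.1, 0.9)), n, 300,
              byrow = TRUE)
  K <- tcrossprod(scale(Z)) / 300
  R <- chol(K + diag(1e-8, n))
  h2 <- sapply(1:20, function(i) {
    u <- drop(t(R) %*% rnorm(n)) * sqrt(0.2)
    y <- u + rnorm(n, 0, sqrt(0.8))
    f <- remlFit(y, K = list(g = K), computeSe = FALSE)
    f$sigma2[[1]] / sum(f$sigma2)
  })
  expect_lt(abs(mean(h2) - 0.2), 0.04)
})

test_that("the boundary LRT mass is one half for a well-separated kernel", {
  # engine-level check of the 0.5 chi0 : 0.5 chi1 mixture: a balanced
  # grouping kernel against a pure-noise null, base model residual-only
  set.seed(19)
  n <- 300
  g <- rep(1:30, each = 10)
  Z <- outer(g, 1:30, "==") + 0
  kern <- precomputeEigen(tcrossprod(Z))
  lrts <- vapply(1:300, function(i) {
    y <- rnorm(n)
    s2 <- sum((y - mean(y))^2) / (n - 1)
    llBase <- -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2) +
                        log(n) + (n - 1))
    f <- remlFit(y, K = list(u = kern), computeSe = FALSE)
    lrtMixtureP(f$loglik, llBase)$lrt
  }, numeric(1))
  expect_gt(mean(lrts == 0), 0.40)
  expect_lt(mean(lrts == 0), 0.60)
  pos <- lrts[lrts > 0]
  ks <- suppressWarnings(ks.test(pos, function(q) pchisq(q, df = 1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("BLUP obeys shrinkage and translation identities", {
  pop <- tinyPop()
  ids <- pop$final$id
  y <- pop$ystar$ystar
  A <- pop$A
  vc0 <- c(a = 1e-12, residual = 1)
  sol0 <- blupSolve(y, K = list(a = A), vc = vc0)
  expect_lt(max(abs(sol0$u$a)), 1e-9)
  vc <- c(a = 0.3, residual = 0.7)
  s1 <- blupSolve(y, K = list(a = A), vc = vc)
  s2 <- blupSolve(y + 5, K = list(a = A), vc = vc)
  expect_equal(s2$beta - s1$beta, 5, tolerance = 1e-8)
  expect_equal(s1$u$a, s2$u$a, tolerance = 1e-8)
  # masked individuals still receive predictions
  ym <- y; ym[1:30] <- NA
  sm <- blupSolve(ym, K = list(a = A), vc = vc)
  expect_true(all(is.finite(sm$u$a[1:30])))
})

test_that("GBLUP with a pedigree kernel equals the Henderson MME solution", {
  pop <- tinyPop()
  ids <- pop$final$id[1:50]
  A <- subsetRel(pop$A, ids)
  y <- pop$ystar$ystar[match(ids, pop$ystar$id)]
  vc <- c(a = 0.25, residual = 0.75)
  ym <- y; ym[41:50] <- NA
  sol <- blupSolve(ym, K = list(a = A), vc = vc)
  orc <- mmeBlupOracle(ym, relMatrix(A), 0.25, 0.75)
  expect_equal(unname(sol$beta), unname(orc$beta), tolerance = 1e-8)
  expect_equal(unname(sol$u$a), unname(orc$u), tolerance = 1e-8)
})
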