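# Synthetic population generator: pedigree structure, Mendelian
# transmission, linkage disequilibrium and trait architecture.

test_that("pedigree has the configured half-sib family structure", {
  cfg <- simConfig(nSires = 3, offspringPerSire = 4, nBreeds = 2,
                   nChromosomes = 1, nSeqVariantsPerChrom = 50, seed = 1)
  ped <- simulatePedigree(cfg)
  off <- ped[ped$generation == 1, ]
  expect_equal(nrow(off), 12)
  expect_equal(unname(table(off$sire)), rep(4L, 3), ignore_attr = TRUE)
  expect_true(all(!is.na(off$sire)))
  # breed proportions propagate as parent means and stay on the simplex
  bcols <- grep("^breed", names(ped), value = TRUE)
  i <- which(ped$generation == 1)[1]
  s <- match(ped$sire[i], ped$id); d <- match(ped$dam[i], ped$id)
  expect_equal(unlist(ped[i, bcols]),
               (unlist(ped[s, bcols]) + unlist(ped[d, bcols])) / 2)
  expect_equal(rowSums(ped[, bcols]), rep(1, nrow(ped)), ignore_attr = TRUE)
})

test_that("a single-generation population consists of founders only", {
  cfg <- simConfig(nSires = 5, offspringPerSire = 3, nGenerations = 1,
                   nChromosomes = 1, nSeqVariantsPerChrom = 50, seed = 2)
  ped <- simulatePedigree(cfg)
  expect_true(all(is.na(ped$sire) & is.na(ped$dam)))
  expect_true(all(ped$generation == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nSires = 0), "positive")
  expect_error(simConfig(qtlH2 = 0.3, totalH2 = 0.2), "qtlH2")
  expect_error(simConfig(breedFst = 1), "breedFst")
  expect_error(simConfig(array50kFraction = 0.5, hdFraction = 0.3), "nest")
})

test_that("genotypes are Mendelian-consistent for every parent-offspring pair", {
  pop <- tinyPop()
  g <- dosages(pop$genotypes)
  off <- pop$final
  for (k in seq_len(nrow(off))) {
    go <- g[off$id[k], ]
    for (par in c(off$sire[k], off$dam[k])) {
      gp <- g[par, ]
      # opposing homozygotes are impossible between parent and offspring
      expect_equal(sum((gp == 0 & go == 2) | (gp == 2 & go == 0)), 0)
    }
  }
})

test_that("linkage disequilibrium decays with distance", {
  pop <- tinyPop()
  mk <- markerMap(pop$genotypes)
  W <- dosages(pop$genotypes)[pop$final$id, mk$chrom == 1]
  pos <- mk$pos[mk$chrom == 1]
  p <- colMeans(W) / 2
  keep <- p > 0.05 & p < 0.95
  W <- W[, keep]; pos <- pos[keep]
  set.seed(9)
  pairs <- cbind(sample(ncol(W), 4000, TRUE), sample(ncol(W), 4000, TRUE))
  pairs <- pairs[pairs[, 1] < pairs[, 2], ]
  d <- pos[pairs[, 2]] - pos[pairs[, 1]]
  r2 <- vapply(seq_len(nrow(pairs)), function(i)
    suppressWarnings(cor(W[, pairs[i, 1]], W[, pairs[i, 2]]))^2, numeric(1))
  bins <- cut(d, breaks = c(0, 2e4, 5e4, 1e5, 3e5, 1e6, Inf))
  m <- tapply(r2, bins, mean, na.rm = TRUE)
  expect_gte(sum(!is.na(m)), 5)
  expect_lt(cor(seq_along(m)[!is.na(m)], m[!is.na(m)],
                method = "spearman"), 0)
  # adjacent variants are in stronger LD than variants 1 Mbp apart
  adj <- mean(vapply(seq_len(ncol(W) - 1), function(j)
    suppressWarnings(cor(W[, j], W[, j + 1]))^2, numeric(1)), na.rm = TRUE)
  expect_gt(adj, mean(r2[d > 1e6], na.rm = TRUE))
})

test_that("no breed differentiation arises when breedFst is zero", {
  cfg <- simConfig(nBreeds = 2, breedFst = 0, nSires = 40,
                   offspringPerSire = 2, nChromosomes = 1,
                   nSeqVariantsPerChrom = 400, seed = 4)
  ped <- simulatePedigree(cfg)
  geno <- simulateGenotypes(ped, cfg)
  fo <- ped[ped$generation == 0, ]
  b <- max.col(as.matrix(fo[, grep("^breed", names(ped))]))
  W <- dosages(geno)[fo$id, ]
  dif <- colMeans(W[b == 1, ]) / 2 - colMeans(W[b == 2, ]) / 2
  expect_lt(abs(mean(dif)), 0.02)
})

test_that("identical seeds reproduce the population bit for bit", {
  cfg <- simConfig(nSires = 10, offspringPerSire = 4, nChromosomes = 1,
                   nSeqVariantsPerChrom = 300, nQtlRegions = 2,
                   nCausalPerRegion = 2, qtlRegionBp = 5e6, seed = 11)
  p1 <- simulatePopulation(cfg)
  p2 <- simulatePopulation(cfg)
  expect_identical(dosages(p1$genotypes), dosages(p2$genotypes))
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_identical(p1$pedigree, p2$pedigree)
})

test_that("trait variance decomposes as configured", {
  pop <- tinyPop()
  vf <- pop$truth$varFractions
  # the causal-region variance is scaled to the target exactly
  expect_equal(unname(vf["qtl"]), pop$config$qtlH2, tolerance = 1e-10)
  # realized heritability approaches the target
  cfg <- simConfig(nSires = 125, offspringPerSire = 16, nChromosomes = 2,
                   nSeqVariantsPerChrom = 1200, qtlRegionBp = 2e6,
                   seed = 21)
  pop2 <- simulatePopulation(cfg)
  expect_lt(abs(pop2$truth$h2Realized - cfg$totalH2), 0.04)
})

test_that("a fully marker-determined trait shows up in single-marker regression", {
  cfg <- simConfig(nSires = 60, offspringPerSire = 8, nChromosomes = 1,
                   nSeqVariantsPerChrom = 600, nQtlRegions = 1,
                   nCausalPerRegion = 1, qtlH2 = 0.3, totalH2 = 0.3,
                   seed = 31)
  pop <- simulatePopulation(cfg)
  cs <- pop$truth$causal
  expect_equal(nrow(cs), 1)
  ys <- adjustPhenotypes(pop$phenotypes)
  w <- dosages(pop$genotypes)[ys$id, cs$id]
  # OLS oracle on the genetic + residual part recovers the full h2
  gpe <- (pop$truth$qtlValue + pop$truth$residual)[ys$id]
  expect_equal(summary(lm(gpe ~ w))$r.squared, 0.3, tolerance = 0.05)
  # after fixed-effect adjustment most of the signal remains (part of the
  # causal variance is collinear with the breed-proportion covariates)
  expect_gt(summary(lm(ys$ystar ~ w))$r.squared, 0.15)
})

test_that("a zero-heritability trait carries no genetic signal", {
  cfg <- simConfig(nSires = 20, offspringPerSire = 4, nChromosomes = 1,
                   nSeqVariantsPerChrom = 200, qtlH2 = 0, totalH2 = 0,
                   seed = 41)
  pop <- simulatePopulation(cfg)
  expect_true(all(pop$truth$qtlValue == 0))
  expect_true(all(pop$truth$polygenicValue == 0))
})
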