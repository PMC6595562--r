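# Scenario-based variant selection and LD pruning.

fakeResults <- function() {
  # 12 variants on one chromosome, alternating HD membership
  m <- 12
  mk <- data.frame(id = sprintf("v%02d", 1:m), chrom = 1,
                   pos = seq(10000, by = 50000, length.out = m),
                   seq = TRUE, hd = rep(c(TRUE, FALSE), 6),
                   array50k = FALSE, stringsAsFactors = FALSE)
  geno <- GenotypeData(matrix(rep(0:2, length.out = 10 * m), 10, m,
                              dimnames = list(sprintf("s%02d", 1:10), NULL)),
                       mk)
  nl <- c(4, 2, 5, 1, 3.5, 0.5, 3, 2.9, 6, 1.2, 0.1, 3.2)
  gwas <- data.frame(id = mk$id, chrom = 1, pos = mk$pos,
                     p = 10^(-nl), neglog10p = nl,
                     stringsAsFactors = FALSE)
  rhm <- data.frame(window = 1:2, chrom = 1,
                    startBp = c(10000, 210000), endBp = c(260000, 460000),
                    neglog10p = c(3.4, 2.1), converged = TRUE,
                    stringsAsFactors = FALSE)
  list(geno = geno, gwas = gwas, rhm = rhm)
}

test_that("selection rules threshold, union and intersect as specified", {
  fx <- fakeResults()
  s1 <- selectVariants(selectionScenario(1), fx$gwas, NULL, fx$geno)
  expect_setequal(s1$id, fx$gwas$id[fx$gwas$neglog10p >= 3])
  # HD panel restriction
  s2 <- selectVariants(selectionScenario(2), fx$gwas, NULL, fx$geno)
  expect_setequal(s2$id, intersect(s1$id, panelVariants(fx$geno, "hd")))
  # all variants within significant windows, overlapping windows counted once
  s3 <- selectVariants(selectionScenario(3), fx$gwas, fx$rhm, fx$geno)
  inWin <- fx$geno@markers$pos >= 10000 & fx$geno@markers$pos <= 260000
  expect_setequal(s3$id, fx$geno@markers$id[inWin])
  expect_equal(anyDuplicated(s3$id), 0)
  # the combined rule is the intersection of both criteria
  s6 <- selectVariants(selectionScenario(6), fx$gwas, fx$rhm, fx$geno)
  expect_setequal(s6$id, intersect(s1$id, s3$id))
  expect_true(all(s6$id %in% s1$id))
  expect_true(all(s6$id %in% s3$id))
  expect_lte(nrow(s6), nrow(s1))
  # an empty selection warns and returns a zero-row set
  gw0 <- fx$gwas; gw0$neglog10p <- 0; gw0$p <- 1
  expect_warning(s0 <- selectVariants(selectionScenario(1), gw0, NULL,
                                      fx$geno), "empty")
  expect_equal(nrow(s0), 0)
})

test_that("overlapping significant windows contribute each variant once", {
  fx <- fakeResults()
  rhm2 <- rbind(fx$rhm,
                data.frame(window = 3, chrom = 1, startBp = 110000,
                           endBp = 360000, neglog10p = 5, converged = TRUE))
  rhm2$neglog10p[2] <- 4
  s <- selectVariants(selectionScenario(3), fx$gwas, rhm2, fx$geno)
  expect_equal(anyDuplicated(s$id), 0)
  expect_setequal(s$id, fx$geno@markers$id[fx$geno@markers$pos <= 460000])
})

test_that("non-converged windows are never used for selection", {
  fx <- fakeResults()
  fx$rhm$converged <- c(FALSE, TRUE)
  expect_warning(
    s <- selectVariants(selectionScenario(3), fx$gwas, fx$rhm, fx$geno),
    "empty")
  expect_equal(nrow(s), 0)
})

test_that("LD pruning keeps the more significant member of a tight pair", {
  set.seed(30)
  n <- 80
  w1 <- rbinom(n, 2, 0.5)
  w2 <- w1                                  # r2 = 1, 1 kbp apart
  w3 <- rbinom(n, 2, 0.5)                   # independent
  W <- cbind(w1, w2, w3)
  mk <- data.frame(id = c("a", "b", "c"), chrom = 1,
                   pos = c(10000, 11000, 90000), seq = TRUE, hd = TRUE,
                   array50k = TRUE, stringsAsFactors = FALSE)
  geno <- GenotypeData(matrix(as.integer(W), n, 3,
                              dimnames = list(sprintf("s%02d", 1:n), mk$id)),
                       mk)
  set <- data.frame(id = c("a", "b", "c"), chrom = 1,
                    pos = mk$pos, gwasP = c(1e-4, 1e-5, 0.5),
                    window = NA_integer_, stringsAsFactors = FALSE)
  pr <- ldPrune(set, geno)
  expect_setequal(pr$id, c("b", "c"))       # keeps the smaller p
  audit <- attr(pr, "audit")
  expect_false(audit$kept[audit$id == "a"])
  # without p-values, the earlier position is kept
  set2 <- set; set2$gwasP <- NA_real_
  expect_setequal(ldPrune(set2, geno)$id, c("a", "c"))
  # mutually independent variants are untouched
  set3 <- set[3, ]
  expect_equal(ldPrune(set3, geno)$id, "c")
})

test_that("no surviving within-window pair reaches the r2 ceiling", {
  pop <- tinyPop()
  mk <- markerMap(pop$genotypes)
  ids <- mk$id[mk$chrom == 1][1:150]
  set <- data.frame(id = ids, chrom = 1,
                    pos = mk$pos[match(ids, mk$id)],
                    gwasP = runif(length(ids)), window = NA_integer_,
                    stringsAsFactors = FALSE)
  gsub <- subsetGenotypes(pop$genotypes, samples = pop$final$id)
  pr <- ldPrune(set, gsub, r2Max = 0.95)
  expect_lte(nrow(pr), nrow(set))
  W <- dosages(subsetGenotypes(gsub, variants = pr$id))
  # exhaustive audit over all surviving pairs within 100 kbp
  for (i in seq_len(nrow(pr) - 1)) {
    for (j in seq.int(i + 1, nrow(pr))) {
      if (pr$pos[j] - pr$pos[i] > 1e5) break
      r2 <- suppressWarnings(cor(W[, i], W[, j]))^2
      if (is.finite(r2)) expect_lt(r2, 0.95)
    }
  }
  # pruning is deterministic
  pr2 <- ldPrune(set, gsub, r2Max = 0.95)
  expect_identical(pr$id, pr2$id)
})

test_that("the scenario table lays out one row per configuration", {
  cv <- list(accuracy = 0.2, accuracySe = 0.01, slope = 0.9,
             slopeSe = 0.02)
  res <- c(list(array50k = list(cv = cv)),
           stats::setNames(lapply(1:7, function(s)
             list(scenario = selectionScenario(s),
                  set = data.frame(id = character(2 * s)), cv = cv)),
             paste0("scenario", 1:7)))
  tab <- scenarioTable(res)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$nSelected[-1], 2 * (1:7))
  expect_true(all(c("accuracy", "slope") %in% names(tab)))
})
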