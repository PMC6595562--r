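# Gene-dropping simulator of a multi-breed half-sib population with nested
# marker panels.  Founder haplotypes follow a Balding-Nichols breed
# differentiation model with a first-order autoregressive latent process
# along the chromosome (linkage disequilibrium decaying with distance);
# meioses place crossovers by a Haldane map at 1 cM per Mbp.

#' Simulate a half-sib pedigree
#'
#' Builds `nGenerations` of a multi-breed pedigree.  Founders are purebred
#' and unrelated; each intermediate generation refreshes the male and female
#' pools by random matings; the final generation consists of `nSires`
#' paternal half-sib families of `offspringPerSire` offspring, one offspring
#' per dam.  Breed proportions propagate as the mean of the parental
#' vectors.
#'
#' @param config a [simConfig()] object
#' @return `data.frame` with columns `id`, `sire`, `dam` (`NA` when
#'   unknown), `generation` (0-based), `sex` (`"M"`/`"F"`) and one
#'   `breed<k>` proportion column per breed; rows ordered parents before
#'   offspring.
#' @export
simulatePedigree <- function(config) {
  validateSimConfig(config)
  if (config$nSires < 1 || config$offspringPerSire < 1)
    stop("invalid config: nSires and offspringPerSire must be positive")
  withSeed(substreamSeed(config$seed, "pedigree"), {
    nS <- config$nSires
    nD <- nS * config$offspringPerSire
    B <- config$nBreeds
    G <- config$nGenerations

    newIds <- function(gen, sex, n)
      sprintf("g%d%s%05d", gen, tolower(sex), seq_len(n))
    founderBreeds <- function(n) {
      b <- matrix(0, n, B)
      b[cbind(seq_len(n), rep_len(seq_len(B), n))] <- 1
      b
    }

    rows <- list()
    addGen <- function(gen, males, females, sires, dams, bprop) {
      n <- length(males) + length(females)
      data.frame(id = c(males, females),
                 sire = sires, dam = dams,
                 generation = gen,
                 sex = rep(c("M", "F"), c(length(males), length(females))),
                 bprop, stringsAsFactors = FALSE)
    }

    # founders
    m0 <- newIds(0, "M", nS); f0 <- newIds(0, "F", nD)
    bp0 <- rbind(founderBreeds(nS), founderBreeds(nD))
    colnames(bp0) <- paste0("breed", seq_len(B))
    rows[[1]] <- addGen(0L, m0, f0, NA_character_, NA_character_,
                        as.data.frame(bp0))
    males <- m0; females <- f0

    if (G >= 2) {
      for (g in seq_len(G - 1L)) {
        final <- (g == G - 1L)
        if (final) {
          sires <- rep(males, each = config$offspringPerSire)
          dams <- sample(females, nD, replace = length(females) < nD)
          ids <- sprintf("g%do%05d", g, seq_len(nD))
          sex <- sample(c("M", "F"), nD, replace = TRUE)
        } else {
          n <- nS + nD
          sires <- sample(males, n, replace = TRUE)
          dams <- sample(females, n, replace = TRUE)
          ids <- c(newIds(g, "M", nS), newIds(g, "F", nD))
          sex <- rep(c("M", "F"), c(nS, nD))
        }
        ped <- do.call(rbind, rows)
        bcols <- paste0("breed", seq_len(B))
        bmat <- as.matrix(ped[, bcols, drop = FALSE])
        rownames(bmat) <- ped$id
        bprop <- (bmat[sires, , drop = FALSE] + bmat[dams, , drop = FALSE]) / 2
        rownames(bprop) <- NULL
        rows[[g + 1L]] <- data.frame(id = ids, sire = sires, dam = dams,
                                     generation = g, sex = sex,
                                     as.data.frame(bprop),
                                     stringsAsFactors = FALSE)
        males <- ids[sex == "M"]; females <- ids[sex == "F"]
      }
    }
    ped <- do.call(rbind, rows)
    rownames(ped) <- NULL
    ped
  })
}

validatePedigree <- function(pedigree) {
  idx <- seq_len(nrow(pedigree))
  pos <- stats::setNames(idx, pedigree$id)
  for (col in c("sire", "dam")) {
    p <- pedigree[[col]]
    known <- !is.na(p)
    if (any(is.na(pos[p[known]])))
      stop("pedigree: unknown ", col, " id")
    if (any(pos[p[known]] >= idx[known]))
      stop("pedigree: parents must precede offspring (cycle or bad order)")
  }
  bcols <- grep("^breed", names(pedigree), value = TRUE)
  if (length(bcols)) {
    s <- rowSums(pedigree[, bcols, drop = FALSE])
    if (any(abs(s - 1) > 1e-8) ||
        any(pedigree[, bcols] < -1e-12))
      stop("pedigree: breed proportions must be nonnegative and sum to 1")
  }
  invisible(pedigree)
}

#' Simulate genotypes through a pedigree
#'
#' Founder haplotypes are drawn per breed under a Balding-Nichols model
#' (ancestral frequencies uniform on (0.05, 0.95), breed drift governed by
#' `breedFst`) with a latent first-order autoregressive process along each
#' chromosome so that linkage disequilibrium decays with distance
#' (`ldDecayBp`).  Haplotypes are then gene-dropped through the pedigree with
#' crossovers placed by a Haldane map (1 cM per Mbp).  Panel membership flags
#' are drawn so that the 50k panel nests inside HD, which nests inside the
#' sequence panel.
#'
#' @param pedigree from [simulatePedigree()]
#' @param config a [simConfig()] object
#' @return a [GenotypeData-class] over all pedigree individuals.
#' @export
simulateGenotypes <- function(pedigree, config) {
  validatePedigree(pedigree)
  withSeed(substreamSeed(config$seed, "genotypes"), {
    n <- nrow(pedigree)
    mC <- config$nSeqVariantsPerChrom
    nChr <- config$nChromosomes
    founder <- is.na(pedigree$sire) & is.na(pedigree$dam)
    # founder breed index = dominant breed (founders are purebred)
    bcols <- grep("^breed", names(pedigree), value = TRUE)
    breedIdx <- max.col(as.matrix(pedigree[, bcols, drop = FALSE]))
    sireIdx <- match(pedigree$sire, pedigree$id)
    damIdx <- match(pedigree$dam, pedigree$id)

    dosage <- matrix(0L, n, mC * nChr,
                     dimnames = list(pedigree$id, NULL))
    markers <- vector("list", nChr)

    for (ch in seq_len(nChr)) {
      pos <- sort(sample.int(config$chromLengthBp - 1L, mC)) + 0L
      p0 <- runif(mC, 0.05, 0.95)
      pb <- matrix(0, config$nBreeds, mC)
      F <- config$breedFst
      for (b in seq_len(config$nBreeds)) {
        pb[b, ] <- if (F > 0)
          stats::rbeta(mC, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
        else p0
      }
      pb <- pmin(pmax(pb, 1e-4), 1 - 1e-4)
      thr <- qnorm(pb)

      h1 <- matrix(0L, n, mC); h2 <- matrix(0L, n, mC)
      # founders: latent AR(1) per haplotype
      fIdx <- which(founder)
      if (length(fIdx)) {
        a <- exp(-diff(pos) / config$ldDecayBp)
        for (hap in 1:2) {
          z <- matrix(rnorm(length(fIdx) * mC), length(fIdx), mC)
          for (j in 2:mC)
            z[, j] <- a[j - 1] * z[, j - 1] + sqrt(1 - a[j - 1]^2) * z[, j]
          alle <- z < matrix(thr[breedIdx[fIdx], ], length(fIdx), mC)
          if (hap == 1) h1[fIdx, ] <- alle + 0L else h2[fIdx, ] <- alle + 0L
        }
      }
      # gene dropping
      morgans <- config$chromLengthBp / 1e8
      meiosis <- function(pi) {
        nx <- rpois(1L, morgans)
        phase <- rbinom(1L, 1L, 0.5)
        if (nx == 0L) {
          if (phase == 0L) h1[pi, ] else h2[pi, ]
        } else {
          xo <- sort(runif(nx, 0, config$chromLengthBp))
          seg <- (phase + findInterval(pos, xo)) %% 2L
          ifelse(seg == 0L, h1[pi, ], h2[pi, ])
        }
      }
      for (i in which(!founder)) {
        h1[i, ] <- if (is.na(sireIdx[i])) {
          # unknown parent: draw a population haplotype for the individual's
          # breed mixture via the majority breed
          (rnorm(mC) < thr[breedIdx[i], ]) + 0L
        } else meiosis(sireIdx[i])
        h2[i, ] <- if (is.na(damIdx[i])) {
          (rnorm(mC) < thr[breedIdx[i], ]) + 0L
        } else meiosis(damIdx[i])
      }
      cols <- (ch - 1L) * mC + seq_len(mC)
      dosage[, cols] <- h1 + h2

      hdIdx <- sort(sample.int(mC, round(config$hdFraction * mC)))
      k50Idx <- sort(sample(hdIdx, round(config$array50kFraction * mC)))
      markers[[ch]] <- data.frame(
        id = sprintf("c%d_v%05d", ch, seq_len(mC)),
        chrom = ch, pos = pos,
        seq = TRUE,
        hd = seq_len(mC) %in% hdIdx,
        array50k = seq_len(mC) %in% k50Idx,
        freq = colMeans(dosage[founder, cols, drop = FALSE]) / 2,
        stringsAsFactors = FALSE)
    }
    markers <- do.call(rbind, markers)
    if (config$missingRate > 0) {
      nm <- length(dosage)
      miss <- which(runif(nm) < config$missingRate)
      dosage[miss] <- NA_integer_
    }
    colnames(dosage) <- markers$id
    GenotypeData(dosage, markers)
  })
}

#' Simulate phenotypes and the trait truth record
#'
#' The trait (a worm-egg-count-like variable treated as Gaussian on an
#' implicit transformed scale) is composed of fixed effects, a causal-region
#' genetic value, a pedigree polygenic value and residual noise:
#' `y = mu + fixed + sum_q W_q beta_q + a + e`.  Causal variants are drawn in
#' `nQtlRegions` clusters and their joint effect is scaled to explain exactly
#' `qtlH2` of the (unit) phenotypic variance; the polygenic term carries
#' variance `totalH2 - qtlH2` and is propagated through the pedigree.
#' Contemporary-group effects are drawn with variance half the residual
#' variance and enter as fixed effects.
#'
#' @param geno [GenotypeData-class] over the pedigree individuals
#' @param pedigree from [simulatePedigree()]
#' @param config a [simConfig()] object
#' @param seed trait-replicate seed; defaults to the config's phenotype
#'   substream, override to draw further trait realisations on the same
#'   genotypes
#' @return list with `phenotypes` (one row per final-generation individual:
#'   `id`, `y`, covariates) and `truth` (causal table, per-individual genetic
#'   values, realised variance fractions).
#' @export
simulatePhenotypes <- function(geno, pedigree, config,
                               seed = substreamSeed(config$seed, "phenotypes")) {
  validatePedigree(pedigree)
  withSeed(seed, {
    final <- pedigree$generation == max(pedigree$generation)
    ids <- pedigree$id[final]
    n <- length(ids)
    mk <- markerMap(geno)
    W <- dosages(geno)

    # --- causal architecture -------------------------------------------
    sigmaPoly <- config$totalH2 - config$qtlH2
    sigmaE <- 1 - config$totalH2
    causal <- NULL
    gQtl <- numeric(n)
    if (config$qtlH2 > 0) {
      candidate <- if (config$causalOnArrays) mk$seq else (mk$seq & !mk$hd)
      sub <- W[ids, , drop = FALSE]
      frq <- colMeans(sub, na.rm = TRUE) / 2
      poly <- frq >= 0.05 & frq <= 0.95 & colSums(is.na(sub)) == 0
      candidate <- candidate & poly
      regions <- list()
      chroms <- rep_len(sample(unique(mk$chrom)), config$nQtlRegions)
      for (q in seq_len(config$nQtlRegions)) {
        ok <- FALSE
        for (try in 1:100) {
          ch <- chroms[q]
          center <- runif(1, config$qtlRegionBp / 2,
                          config$chromLengthBp - config$qtlRegionBp / 2)
          inReg <- which(candidate & mk$chrom == ch &
                           abs(mk$pos - center) <= config$qtlRegionBp / 2)
          if (length(inReg) >= config$nCausalPerRegion) {
            pick <- sort(sample(inReg, config$nCausalPerRegion))
            candidate[pick] <- FALSE   # regions do not share causals
            regions[[q]] <- data.frame(region = q, idx = pick)
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("simulatePhenotypes: could not place causal region ", q,
                      " (too few eligible sequence-only variants); ",
                      "increase density or region width")
      }
      regions <- do.call(rbind, regions)
      beta <- rnorm(nrow(regions))
      g0 <- as.vector(sub[, regions$idx, drop = FALSE] %*% beta)
      if (var(g0) <= 0)
        stop("simulatePhenotypes: requested qtlH2 unattainable - causal ",
             "variants carry no variance in the phenotyped generation")
      s <- sqrt(config$qtlH2 / var(g0))
      beta <- beta * s
      gQtl <- g0 * s - mean(g0 * s)
      causal <- data.frame(id = mk$id[regions$idx],
                           chrom = mk$chrom[regions$idx],
                           pos = mk$pos[regions$idx],
                           region = regions$region, beta = beta,
                           stringsAsFactors = FALSE)
    }

    # --- polygenic values down the pedigree ----------------------------
    a <- numeric(nrow(pedigree))
    if (sigmaPoly > 0) {
      sIdx <- match(pedigree$sire, pedigree$id)
      dIdx <- match(pedigree$dam, pedigree$id)
      sdP <- sqrt(sigmaPoly)
      for (i in seq_len(nrow(pedigree))) {
        s <- sIdx[i]; d <- dIdx[i]
        if (is.na(s) && is.na(d)) a[i] <- rnorm(1, 0, sdP)
        else if (is.na(s)) a[i] <- 0.5 * a[d] + rnorm(1, 0, sdP * sqrt(0.75))
        else if (is.na(d)) a[i] <- 0.5 * a[s] + rnorm(1, 0, sdP * sqrt(0.75))
        else a[i] <- 0.5 * (a[s] + a[d]) + rnorm(1, 0, sdP * sqrt(0.5))
      }
    }
    aFinal <- a[final]

    # --- fixed effects --------------------------------------------------
    age <- sample(79:214, n, replace = TRUE)
    damAge <- sample(2:8, n, replace = TRUE)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    rbLevels <- c("11", "21", "22", "32")
    rearingBirth <- sample(rbLevels, n, replace = TRUE,
                           prob = c(0.45, 0.15, 0.3, 0.1))
    # sire families are deliberately spread across contemporary groups
    # (site x year x management), mirroring across-flock genetic linkage
    cg <- sample(ceiling(seq_len(n) / config$cgBlock))
    cgEff <- rnorm(max(cg), 0, sqrt(0.5 * sigmaE))
    bcols <- grep("^breed", names(pedigree), value = TRUE)
    bprop <- as.matrix(pedigree[final, bcols, drop = FALSE])
    betaBreed <- seq(-0.25, 0.25, length.out = length(bcols))
    fixed <- 0.005 * (age - mean(age)) +
      0.02 * (damAge - mean(damAge)) +
      0.1 * (sex == "M") +
      c(0, 0.1, 0.15, 0.2)[match(rearingBirth, rbLevels)] +
      cgEff[cg] +
      as.vector(bprop %*% betaBreed)

    e <- rnorm(n, 0, sqrt(sigmaE))
    y <- 10 + fixed + gQtl + aFinal + e

    phen <- data.frame(id = ids, y = y, age = age, damAge = damAge,
                       sex = sex, rearingBirth = rearingBirth, cg = cg,
                       as.data.frame(bprop, row.names = NULL),
                       stringsAsFactors = FALSE)
    g <- gQtl + aFinal
    truth <- list(causal = causal,
                  qtlValue = stats::setNames(gQtl, ids),
                  polygenicValue = stats::setNames(aFinal, ids),
                  residual = stats::setNames(e, ids),
                  varFractions = c(qtl = var(gQtl), polygenic = var(aFinal),
                                   residual = var(e)),
                  h2Realized = var(g) / (var(g) + var(e)),
                  qtlH2 = config$qtlH2, totalH2 = config$totalH2)
    list(phenotypes = phen, truth = truth)
  })
}

#' Simulate a complete study population
#'
#' Convenience wrapper chaining [simulatePedigree()], [simulateGenotypes()]
#' and [simulatePhenotypes()].
#'
#' @param config a [simConfig()] object
#' @return list with `pedigree`, `genotypes`, `phenotypes`, `truth`.
#' @export
simulatePopulation <- function(config) {
  ped <- simulatePedigree(config)
  geno <- simulateGenotypes(ped, config)
  ph <- simulatePhenotypes(geno, ped, config)
  list(pedigree = ped, genotypes = geno,
       phenotypes = ph$phenotypes, truth = ph$truth)
}
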