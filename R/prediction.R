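# Discovery/training splitting, sire-family cross-validation folds,
# two-component GBLUP prediction and accuracy/bias evaluation.

#' Split phenotyped individuals into discovery and training/validation sets
#'
#' Whole sire families are assigned to one side so that QTL discovery and
#' predictive evaluation never share family information.  Families are
#' stratified by their dominant breed and drawn at random within stratum
#' until the discovery side reaches its target share, keeping breed
#' proportions close on both sides.
#'
#' @param phenotypes phenotype table (`id` column) of all phenotyped
#'   individuals
#' @param pedigree pedigree providing `sire` and breed proportions
#' @param discoveryFraction fraction of individuals on the discovery side
#'   (study value 6431/10931)
#' @param seed integer seed
#' @param tolerance allowed per-breed proportion difference between sides
#'   (warning when exceeded; default 0.02)
#' @return list with `discovery` and `training` id vectors and
#'   `breedProportions` (per-side means).
#' @export
makeSplit <- function(phenotypes, pedigree, discoveryFraction = 6431 / 10931,
                      seed = 1L, tolerance = 0.02) {
  ids <- phenotypes$id
  pi <- match(ids, pedigree$id)
  sire <- pedigree$sire[pi]
  sire[is.na(sire)] <- paste0("nofam_", ids[is.na(sire)])
  bcols <- grep("^breed", names(pedigree), value = TRUE)
  bprop <- as.matrix(pedigree[pi, bcols, drop = FALSE])

  fam <- split(seq_along(ids), sire)
  famBreed <- vapply(fam, function(j)
    which.max(colMeans(bprop[j, , drop = FALSE])), integer(1))
  withSeed(substreamSeed(seed, "split"), {
    disc <- logical(length(ids))
    for (b in unique(famBreed)) {
      fb <- sample(names(fam)[famBreed == b])
      target <- discoveryFraction * sum(lengths(fam[fb]))
      got <- 0
      for (f in fb) {
        if (got >= target) break
        disc[fam[[f]]] <- TRUE
        got <- got + length(fam[[f]])
      }
    }
    pd <- colMeans(bprop[disc, , drop = FALSE])
    pt <- colMeans(bprop[!disc, , drop = FALSE])
    if (any(abs(pd - pt) > tolerance))
      warning("makeSplit: breed proportions differ by more than ",
              tolerance, " between sets (family constraint)")
    list(discovery = ids[disc], training = ids[!disc],
         breedProportions = rbind(discovery = pd, training = pt))
  })
}

#' Build replicated sire-family cross-validation folds
#'
#' Shuffled sire families are greedily packed into `k` folds (each new
#' family joins the currently smallest fold), so folds are disjoint, cover
#' the training/validation set, and never split a paternal half-sib family.
#' Each replicate reshuffles with a derived seed.
#'
#' @param trainingIds ids of the training/validation subset
#' @param pedigree pedigree providing `sire`
#' @param k folds per replicate (default 10)
#' @param nReplicates number of replicate fold layouts (default 10)
#' @param seed integer root seed
#' @return list of replicates; each is a list of `k` id vectors.
#' @export
makeFolds <- function(trainingIds, pedigree, k = 10, nReplicates = 10,
                      seed = 1L) {
  if (k < 2) stop("makeFolds: k must be at least 2 (k = 1 leaves no training data)")
  sire <- pedigree$sire[match(trainingIds, pedigree$id)]
  sire[is.na(sire)] <- paste0("nofam_", trainingIds[is.na(sire)])
  fam <- split(trainingIds, sire)
  if (length(fam) < k)
    stop("makeFolds: fewer sire families than folds")
  n <- length(trainingIds)
  if (any(lengths(fam) > 2 * n / k))
    warning("makeFolds: a sire family exceeds 2n/k; its fold will be oversized")
  lapply(seq_len(nReplicates), function(r) {
    withSeed(substreamSeed(seed, "folds", r), {
      ord <- sample(names(fam))
      folds <- rep(list(character()), k)
      sizes <- rep(0L, k)
      for (f in ord) {
        tgt <- which.min(sizes)
        folds[[tgt]] <- c(folds[[tgt]], fam[[f]])
        sizes[tgt] <- sizes[tgt] + length(fam[[f]])
      }
      folds
    })
  })
}

#' GBLUP prediction with one or more genomic components
#'
#' REML fit plus BLUP solve of `y* = mu + sum_i u_i + e` over the training
#' records, returning per-component predictions for every individual in the
#' relationship matrices, including those whose response was masked (the
#' validation animals).  In the two-component model of the preselection
#' workflow the first GRM is built from the array variants excluding the
#' selected ones, and the second from the selected (top) variants; the total
#' breeding value is the elementwise sum of the component predictions.
#'
#' @param ystar adjusted phenotypes over all individuals (`id`, `ystar`)
#' @param grmList named list of [RelationshipMatrix-class] objects covering
#'   all individuals in `ystar`
#' @param validationIds ids whose phenotypes are masked during fitting
#' @param init optional REML starting values
#' @return list with `fit` (the [remlFit()] on training records), `gebv`
#'   (`data.frame`: id, one column per component, `total`), and `collapsed`
#'   (`TRUE` when a component was pinned at zero).
#' @export
gblupPredict <- function(ystar, grmList, validationIds = character(),
                         init = NULL) {
  ids <- ystar$id
  mask <- ids %in% validationIds
  yAll <- ystar$ystar
  yTrain <- yAll[!mask]
  trainIds <- ids[!mask]
  Ktrain <- lapply(grmList, function(g) subsetRel(g, trainIds))
  fit <- remlFit(yTrain, K = Ktrain, init = init, computeSe = FALSE)
  yMasked <- yAll
  yMasked[mask] <- NA
  Kall <- lapply(grmList, function(g) subsetRel(g, ids))
  sol <- blupSolve(yMasked, K = Kall, vc = fit)
  gebv <- data.frame(id = ids, as.data.frame(sol$u), total = sol$total,
                     stringsAsFactors = FALSE)
  k <- length(grmList)
  collapsed <- any(fit$sigma2[seq_len(k)] == 0)
  if (collapsed && k > 1)
    message("gblupPredict: a genomic component was pinned at zero; ",
            "the model collapsed to fewer components")
  list(fit = fit, gebv = gebv, collapsed = collapsed)
}

#' Variance fraction captured by the preselected variants
#'
#' For the two-component model, `h2_top = s2_top / (s2_top + s2_50k + s2_e)`.
#' When the fit carries an average-information matrix, a delta-method
#' standard error is attached.
#'
#' @param vc a [remlFit()] from the two-component model; the top component
#'   is identified by name (`top`) or taken as the second component
#' @return named list `h2top` (+ `se` when available).
#' @export
h2Top <- function(vc) {
  s2 <- vc$sigma2
  iTop <- if ("top" %in% names(s2)) which(names(s2) == "top") else 2L
  tot <- sum(s2)
  h2 <- as.numeric(s2[iTop] / tot)
  out <- list(h2top = h2)
  if (!is.null(vc$ai)) {
    V <- tryCatch(solve(vc$ai), error = function(e) NULL)
    if (!is.null(V)) {
      grad <- rep(-h2 / tot, length(s2))
      grad[iTop] <- (tot - s2[iTop]) / tot^2
      out$se <- sqrt(as.numeric(t(grad) %*% V %*% grad))
    }
  }
  out
}

#' Replicated sire-family cross-validation of genomic prediction
#'
#' For every fold of every replicate, validation phenotypes are masked, the
#' model is refitted on the remaining records only (no validation phenotype
#' reaches the variance-component estimation) and breeding values are
#' predicted.  Accuracy is `cor(GEBV, y*) / sqrt(h2)` over the validation
#' animals with `h2` supplied from a whole-population fit; the dispersion
#' slope is the regression coefficient of `y*` on GEBV.  Replicate means
#' are averaged and their SD across replicates forms the reported SE.
#'
#' @param ystar adjusted phenotypes of the training/validation subset
#' @param grmList named list of [RelationshipMatrix-class] over that subset
#' @param folds replicate fold layouts from [makeFolds()]
#' @param h2 heritability used in the accuracy denominator (estimated once
#'   on all phenotyped animals)
#' @return a `cvReport` list: `accuracy`, `accuracySe`, `slope`, `slopeSe`,
#'   `h2`, `byReplicate` (`data.frame`), `byFold` (`data.frame`).
#' @export
evaluateCv <- function(ystar, grmList, folds, h2) {
  stopifnot(h2 > 0)
  perFold <- list()
  init <- NULL
  for (r in seq_along(folds)) {
    for (f in seq_along(folds[[r]])) {
      valIds <- folds[[r]][[f]]
      stopifnot(all(valIds %in% ystar$id))
      pred <- gblupPredict(ystar, grmList, validationIds = valIds,
                           init = init)
      init <- pred$fit$sigma2  # warm start within the replicate stream
      v <- pred$gebv$id %in% valIds
      gv <- pred$gebv$total[v]
      yv <- ystar$ystar[match(pred$gebv$id[v], ystar$id)]
      # folds whose GEBV carry (numerically) no variation are degenerate
      ok <- sd(gv) > 1e-6 * sd(yv)
      acc <- if (ok) cor(gv, yv) / sqrt(h2) else NA_real_
      slp <- if (ok) unname(coef(lm(yv ~ gv))[2]) else NA_real_
      if (is.na(acc))
        warning("evaluateCv: zero-variance GEBV in replicate ", r,
                " fold ", f, "; fold excluded")
      perFold[[length(perFold) + 1]] <-
        data.frame(replicate = r, fold = f, n = length(valIds),
                   accuracy = acc, slope = slp)
    }
  }
  byFold <- do.call(rbind, perFold)
  byRep <- do.call(rbind, lapply(split(byFold, byFold$replicate),
                                 function(d) data.frame(
                                   replicate = d$replicate[1],
                                   accuracy = mean(d$accuracy, na.rm = TRUE),
                                   slope = mean(d$slope, na.rm = TRUE))))
  nrep <- nrow(byRep)
  out <- list(accuracy = mean(byRep$accuracy, na.rm = TRUE),
              accuracySe = if (nrep > 1)
                sd(byRep$accuracy, na.rm = TRUE) / sqrt(nrep)
              else NA_real_,
              slope = mean(byRep$slope, na.rm = TRUE),
              slopeSe = if (nrep > 1)
                sd(byRep$slope, na.rm = TRUE) / sqrt(nrep)
              else NA_real_,
              h2 = h2, byReplicate = byRep, byFold = byFold)
  class(out) <- "cvReport"
  out
}

#' @export
print.cvReport <- function(x, ...) {
  cat(sprintf("Cross-validation over %d replicates (h2 = %.3f):\n",
              nrow(x$byReplicate), x$h2))
  cat(sprintf("  accuracy: %.3f +/- %.3f\n", x$accuracy, x$accuracySe))
  cat(sprintf("  slope:    %.3f +/- %.3f\n", x$slope, x$slopeSe))
  invisible(x)
}
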