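# Fixed-effect pre-adjustment, single-variant mixed-model GWAS, and the
# regional heritability mapping genome scan with bp-window refinement.

#' Pre-adjust phenotypes for fixed effects
#'
#' Ordinary least squares of the trait on age (covariate), dam age
#' (covariate), sex, rearing-by-birth type, contemporary group (factors) and
#' breed-proportion covariates (one breed column dropped against the
#' sum-to-one constraint).  The residuals `y*` are the adjusted phenotypes
#' used by every downstream mixed model.
#'
#' @param phenotypes `data.frame` with columns `id`, `y`, `age`, `damAge`,
#'   `sex`, `rearingBirth`, `cg` and `breed*` proportion columns (as emitted
#'   by [simulatePhenotypes()])
#' @return `data.frame` with `id` and `ystar`; the fitted formula is
#'   attached as attribute `"formula"`.
#' @export
adjustPhenotypes <- function(phenotypes) {
  ph <- phenotypes
  bcols <- grep("^breed", names(ph), value = TRUE)
  if (length(bcols) > 1) bcols <- bcols[-1]  # drop one: proportions sum to 1
  covars <- intersect(c("age", "damAge"), names(ph))
  # constant covariates carry no information
  covars <- covars[vapply(covars, function(v) var(ph[[v]]) > 0, logical(1))]
  facs <- intersect(c("sex", "rearingBirth", "cg"), names(ph))
  for (f in facs) ph[[f]] <- factor(ph[[f]])
  # degenerate factors (a single level) carry no information
  facs <- facs[vapply(facs, function(f) nlevels(ph[[f]]) > 1, logical(1))]
  terms <- c(covars, facs, bcols)
  form <- stats::as.formula(paste("y ~",
                                  if (length(terms))
                                    paste(terms, collapse = " + ")
                                  else "1"))
  mm <- model.matrix(form, data = ph)
  qd <- qr(mm)
  if (qd$rank < ncol(mm)) {
    aliased <- colnames(mm)[setdiff(seq_len(ncol(mm)),
                                    qd$pivot[seq_len(qd$rank)])]
    stop("adjustPhenotypes: rank-deficient fixed-effect design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  fit <- lm(form, data = ph)
  out <- data.frame(id = ph$id, ystar = as.vector(residuals(fit)),
                    stringsAsFactors = FALSE)
  attr(out, "formula") <- form
  # raw response and covariate design (sans intercept), for callers that
  # prefer the one-step model with covariates fitted inside the mixed model
  attr(out, "response") <- ph$y
  attr(out, "design") <- mm[, -1, drop = FALSE]
  out
}

#' Single-variant mixed-model GWAS with a Wald test
#'
#' Tests each variant with the model `y* = mu + w g + a + e`, where `a` has
#' covariance proportional to the pedigree relationship matrix.  In `fast`
#' mode the null-model variance components are estimated once and every
#' variant is tested by generalised least squares at that fixed covariance;
#' in `exact` mode the components are re-estimated per variant on the
#' eigen-rotated data.  The Wald statistic `g^2 / se^2` is referred to
#' chi-square with 1 df.
#'
#' @param ystar adjusted phenotypes (`data.frame` with `id`, `ystar`)
#' @param geno [GenotypeData-class] covering the phenotyped individuals
#' @param A pedigree [RelationshipMatrix-class] (or any kernel) over the
#'   phenotyped individuals
#' @param mode `"fast"` (single null REML, GLS per variant) or `"exact"`
#'   (per-variant REML)
#' @param variants optional variant id subset to test
#' @param covariates optional fixed-effect design matrix (rows matching
#'   `ystar`) fitted inside the mixed model; the one-step alternative to
#'   pre-adjustment, exact in finite samples where the two-step shortcut is
#'   mildly conservative (see the methods vignette)
#' @param nullFit optional precomputed null-model [remlFit()]
#' @return `data.frame`: `id`, `chrom`, `pos`, `af`, `beta`, `se`, `wald`,
#'   `p`, `neglog10p`; monomorphic variants yield `NA` rows.  The null-model
#'   fit is attached as attribute `"nullFit"`.
#' @export
runGwas <- function(ystar, geno, A, mode = c("fast", "exact"),
                    variants = NULL, covariates = NULL, nullFit = NULL) {
  mode <- match.arg(mode)
  ids <- ystar$id
  g <- subsetGenotypes(geno, samples = ids, variants = variants)
  W <- dosages(g)
  if (anyNA(W)) stop("runGwas: dosages must be complete")
  mk <- markerMap(g)
  y <- ystar$ystar
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1) else
    cbind(1, as.matrix(covariates))
  Arel <- if (methods::is(A, "RelationshipMatrix")) subsetRel(A, ids) else A
  kern <- normalizeKernel(Arel, n)
  E <- kernelEigen(kern)
  kern$eigen <- E
  if (is.null(nullFit))
    nullFit <- remlFit(y, X = X, K = list(animal = kern), computeSe = FALSE)
  lam <- pmax(E$values, 0)
  U <- E$vectors
  yt <- as.vector(crossprod(U, y))
  Wt <- crossprod(U, W)
  Xt <- crossprod(U, X)

  af <- colMeans(W) / 2
  mono <- af <= 0 | af >= 1
  beta <- se <- rep(NA_real_, ncol(W))

  if (mode == "fast") {
    v <- nullFit$sigma2[1] * lam + nullFit$sigma2["residual"]
    d <- 1 / v
    XtD <- Xt * d
    S <- crossprod(Xt, XtD)
    Sinv <- solve(S)
    ax <- crossprod(XtD, Wt)                       # p x m
    bx <- crossprod(XtD, yt)                       # p
    wDw <- colSums(Wt^2 * d)
    wDy <- as.vector(crossprod(Wt * d, yt))
    denom <- wDw - colSums(ax * (Sinv %*% ax))
    numer <- wDy - as.vector(crossprod(ax, Sinv %*% bx))
    ok <- !mono & denom > .Machine$double.eps * max(wDw)
    beta[ok] <- numer[ok] / denom[ok]
    se[ok] <- sqrt(1 / denom[ok])
  } else {
    for (j in which(!mono)) {
      Xj <- cbind(Xt, Wt[, j])
      fit <- remlRotatedMarker(yt, Xj, lam)
      beta[j] <- fit$beta[ncol(Xj)]
      se[j] <- fit$se2
    }
  }
  wald <- (beta / se)^2
  p <- pchisq(wald, df = 1, lower.tail = FALSE)
  res <- data.frame(id = mk$id, chrom = mk$chrom, pos = mk$pos, af = af,
                    beta = beta, se = se, wald = wald, p = p,
                    neglog10p = -log10(p), stringsAsFactors = FALSE)
  attr(res, "nullFit") <- nullFit
  res
}

# per-marker REML on eigen-rotated data: profile likelihood in h, then GLS
remlRotatedMarker <- function(yt, Xt, lam) {
  n <- length(yt)
  p <- ncol(Xt)
  prof <- function(h) {
    sig <- h * lam + (1 - h)
    w <- 1 / sig
    XtWX <- crossprod(Xt, Xt * w)
    cX <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(cX)) return(-Inf)
    b <- backsolve(cX, forwardsolve(t(cX), crossprod(Xt, w * yt)))
    q <- sum(w * (yt - Xt %*% b)^2)
    -0.5 * ((n - p) * log(q / (n - p)) + sum(log(sig)) +
              2 * sum(log(diag(cX))))
  }
  h <- optimize(prof, c(0, 1 - 1e-8), maximum = TRUE, tol = 1e-6)$maximum
  if (prof(0) >= prof(h)) h <- 0
  sig <- h * lam + (1 - h)
  w <- 1 / sig
  XtWX <- crossprod(Xt, Xt * w)
  b <- solve(XtWX, crossprod(Xt, w * yt))
  q <- sum(w * (yt - Xt %*% b)^2)
  s2 <- q / (n - p)
  covb <- solve(XtWX) * s2
  list(beta = as.vector(b), se2 = sqrt(covb[p, p]))
}

#' Regional heritability mapping genome scan
#'
#' Slides a window of `windowSnps` sequence-panel variants along each
#' chromosome in steps of `stepSnps`, fits the full model (regional GRM +
#' pedigree + residual) and compares it with the base model (pedigree +
#' residual, fitted once) by the boundary-mixture likelihood-ratio test.
#' The regional heritability is `h2_u = s2_u / (s2_u + s2_a + s2_e)` with
#' all three components taken from the full model of that window.  The last
#' window on each chromosome is truncated and kept if it still holds
#' `minVariants` variants.  Windows whose optimizer did not converge are
#' reported flagged and are excluded from downstream selection by default.
#'
#' @param ystar adjusted phenotypes (`data.frame` with `id`, `ystar`)
#' @param geno [GenotypeData-class] covering the phenotyped individuals
#' @param A pedigree [RelationshipMatrix-class] over those individuals
#' @param windowSnps window size in sequence variants (study default 12000,
#'   about 1 Mbp at sequence density)
#' @param stepSnps step in variants (study default 6000)
#' @param panel marker panel scanned (default `"seq"`)
#' @param covariates optional fixed-effect design fitted inside the models
#'   (one-step alternative to pre-adjustment)
#' @param minVariants minimum polymorphic variants per window
#' @return `data.frame` with one row per window: `window`, `chrom`,
#'   `startIdx`, `endIdx`, `startBp`, `endBp`, `midBp`, `nVar`, `sigma2u`,
#'   `sigma2a`, `sigma2e`, `h2Region`, `lrt`, `p`, `neglog10p`,
#'   `converged`.  The base-model fit is attached as attribute `"baseFit"`.
#' @export
rhmScan <- function(ystar, geno, A, windowSnps = 12000, stepSnps = 6000,
                    panel = "seq", covariates = NULL, minVariants = 20) {
  ids <- ystar$id
  y <- ystar$ystar
  X <- if (is.null(covariates)) matrix(1, length(y), 1) else
    cbind(1, as.matrix(covariates))
  g <- subsetGenotypes(geno, samples = ids,
                       variants = markerMap(geno)$id[markerMap(geno)[[panel]]])
  mk <- markerMap(g)
  Arel <- if (methods::is(A, "RelationshipMatrix")) subsetRel(A, ids) else A
  kern <- normalizeKernel(Arel, length(y))
  kern$eigen <- kernelEigen(kern)
  baseFit <- remlFit(y, X = X, K = list(animal = kern), computeSe = FALSE)

  rows <- list()
  wix <- 0L
  for (ch in unique(mk$chrom)) {
    jch <- which(mk$chrom == ch)
    wins <- slidingWindows(length(jch), windowSnps, stepSnps, unit = "count")
    for (r in seq_len(nrow(wins))) {
      j <- jch[wins$start[r]:wins$end[r]]
      wix <- wix + 1L
      rows[[wix]] <- rhmFitWindow(y, g, j, kern, baseFit, minVariants,
                                  window = wix, chrom = ch,
                                  startIdx = wins$start[r],
                                  endIdx = wins$end[r], X = X)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseFit") <- baseFit
  out
}

# fit one RHM window (shared by the scan and the refinement pass)
rhmFitWindow <- function(y, g, j, kernA, baseFit, minVariants, window,
                         chrom, startIdx = NA, endIdx = NA, X = NULL) {
  mk <- markerMap(g)
  row <- data.frame(window = window, chrom = chrom,
                    startIdx = startIdx, endIdx = endIdx,
                    startBp = min(mk$pos[j]), endBp = max(mk$pos[j]),
                    midBp = (min(mk$pos[j]) + max(mk$pos[j])) / 2,
                    nVar = length(j), sigma2u = NA_real_,
                    sigma2a = NA_real_, sigma2e = NA_real_,
                    h2Region = NA_real_, lrt = NA_real_, p = NA_real_,
                    neglog10p = NA_real_, converged = FALSE)
  W <- dosages(g)[, j, drop = FALSE]
  p <- colMeans(W) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < minVariants) return(row)
  W <- W[, poly, drop = FALSE]
  p <- p[poly]
  cc <- 2 * sum(p * (1 - p))
  Z <- sweep(W, 2, 2 * p) / sqrt(cc)
  init <- c(baseFit$sigma2[1], 0.05 * baseFit$sigma2["residual"],
            0.95 * baseFit$sigma2["residual"])
  fit <- tryCatch(
    remlFit(y, X = X, K = list(animal = kernA, region = list(Z = Z)),
            init = init, computeSe = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(row)
  lr <- lrtMixtureP(fit$loglik, baseFit$loglik)
  s2 <- fit$sigma2
  row$sigma2u <- s2[["region"]]
  row$sigma2a <- s2[["animal"]]
  row$sigma2e <- s2[["residual"]]
  row$h2Region <- s2[["region"]] / sum(s2[c("region", "animal", "residual")])
  row$lrt <- lr$lrt
  row$p <- lr$p
  row$neglog10p <- -log10(lr$p)
  row$converged <- fit$converged
  row
}

#' Refine selected RHM regions with bp-defined windows per marker panel
#'
#' Re-tiles each selected region (windows whose `-log10(p)` reached the
#' threshold in the main scan) into non-overlapping bp windows (study
#' default 250 kbp) and fits the regional model per window for each
#' requested marker panel, allowing mapping-precision comparison across
#' densities.  Windows are positioned at their midpoints for reporting.
#'
#' @param scan result of [rhmScan()] (its `"baseFit"` attribute is reused)
#' @param ystar,geno,A as in [rhmScan()]
#' @param threshold `-log10(p)` selection threshold (study default 3);
#'   non-converged scan windows are never selected
#' @param windowBp refinement window size in bp (study default 250000)
#' @param panels marker panels to refine with
#' @param covariates optional fixed-effect design fitted inside the models
#' @param minVariants minimum polymorphic variants per refinement window
#' @return `data.frame` as [rhmScan()] plus columns `panel` and `region`
#'   (index of the merged scan region the window refines).
#' @export
rhmRefine <- function(scan, ystar, geno, A, threshold = 3,
                      windowBp = 250000,
                      panels = c("array50k", "hd", "seq"),
                      covariates = NULL, minVariants = 20) {
  sel <- scan[!is.na(scan$neglog10p) & scan$neglog10p >= threshold &
                scan$converged, , drop = FALSE]
  if (nrow(sel) == 0)
    return(cbind(scan[0, ], panel = character(), region = integer()))
  regions <- mergeRegions(sel)
  ids <- ystar$id
  y <- ystar$ystar
  X <- if (is.null(covariates)) matrix(1, length(y), 1) else
    cbind(1, as.matrix(covariates))
  Arel <- if (methods::is(A, "RelationshipMatrix")) subsetRel(A, ids) else A
  kern <- normalizeKernel(Arel, length(y))
  kern$eigen <- kernelEigen(kern)
  baseFit <- attr(scan, "baseFit")
  if (is.null(baseFit))
    baseFit <- remlFit(y, X = X, K = list(animal = kern), computeSe = FALSE)

  rows <- list()
  wix <- 0L
  for (pn in panels) {
    gp <- subsetGenotypes(geno, samples = ids,
                          variants = markerMap(geno)$id[markerMap(geno)[[pn]]])
    mkp <- markerMap(gp)
    for (r in seq_len(nrow(regions))) {
      span <- regions$endBp[r] - regions$startBp[r] + 1
      wins <- slidingWindows(span, windowBp, windowBp, unit = "bp")
      for (w in seq_len(nrow(wins))) {
        lo <- regions$startBp[r] + wins$start[w] - 1
        hi <- regions$startBp[r] + wins$end[w] - 1
        j <- which(mkp$chrom == regions$chrom[r] & mkp$pos >= lo &
                     mkp$pos <= hi)
        if (length(j) < minVariants) next
        wix <- wix + 1L
        row <- rhmFitWindow(y, gp, j, kern, baseFit, minVariants,
                            window = wix, chrom = regions$chrom[r], X = X)
        row$panel <- pn
        row$region <- r
        rows[[wix]] <- row
      }
    }
  }
  if (length(rows) == 0)
    return(cbind(scan[0, ], panel = character(), region = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseFit") <- baseFit
  out
}

# merge overlapping/adjacent selected windows into regions per chromosome
mergeRegions <- function(sel) {
  sel <- sel[order(sel$chrom, sel$startBp), ]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(sel))) {
    if (!is.null(cur) && sel$chrom[i] == cur$chrom &&
        sel$startBp[i] <= cur$endBp + 1) {
      cur$endBp <- max(cur$endBp, sel$endBp[i])
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- data.frame(chrom = sel$chrom[i], startBp = sel$startBp[i],
                        endBp = sel$endBp[i])
    }
  }
  out[[length(out) + 1]] <- cur
  do.call(rbind, out)
}
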