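# Variant- and sample-level genotype quality control.

#' Quality-control thresholds
#'
#' Defaults follow standard array QC practice: minor allele frequency below
#' 0.01, call rate below 90%, a Hardy-Weinberg chi-square p-value below
#' 1e-15, per-variant heterozygosity more than 3 SD from the panel mean, and
#' sample pairs with dosage correlation at or above 0.99 treated as
#' duplicates.
#'
#' @param mafMin minimum minor allele frequency
#' @param callRateMin minimum variant call rate
#' @param hwePMin minimum Hardy-Weinberg chi-square p-value
#' @param hetSdMax maximum heterozygosity deviation, in SD units
#' @param dupCorMax dosage correlation at/above which samples are duplicates
#' @return a `qcThresholds` list.
#' @export
qcThresholds <- function(mafMin = 0.01, callRateMin = 0.90, hwePMin = 1e-15,
                         hetSdMax = 3, dupCorMax = 0.99) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, callRateMin >= 0, callRateMin <= 1,
            hwePMin >= 0, hwePMin <= 1, hetSdMax > 0,
            dupCorMax > 0, dupCorMax <= 1)
  structure(list(mafMin = mafMin, callRateMin = callRateMin,
                 hwePMin = hwePMin, hetSdMax = hetSdMax,
                 dupCorMax = dupCorMax), class = "qcThresholds")
}

# 1-df chi-square test of Hardy-Weinberg proportions on genotype counts
hweChisqP <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  obs <- cbind(n0, n1, n2)
  chi <- rowSums((obs - e)^2 / pmax(e, .Machine$double.eps))
  # guard monomorphic: expected het 0 and observed 0 -> chi 0
  chi[p %in% c(0, 1)] <- 0
  pchisq(chi, df = 1, lower.tail = FALSE)
}

#' Variant-level quality control
#'
#' Applies, in fixed order, the minor-allele-frequency, call-rate,
#' Hardy-Weinberg (1-df chi-square) and heterozygosity-outlier filters.  A
#' variant failing several criteria is attributed to the first failing one
#' for reporting; the keep mask itself is order-independent.  The
#' heterozygosity filter is computed on the set that already passed the MAF
#' and call-rate filters.  All-missing variants are excluded with their own
#' reason code.
#'
#' @param geno a [GenotypeData-class] object
#' @param thresholds a [qcThresholds()] list
#' @return list with `keep` (logical mask over variants), `reason`
#'   (per-variant factor: `pass`, `all_missing`, `maf`, `call_rate`, `hwe`,
#'   `heterozygosity`) and `counts` (exclusions per criterion, in order).
#' @export
filterVariants <- function(geno, thresholds = qcThresholds()) {
  W <- dosages(geno)
  n <- nrow(W)
  nMiss <- colSums(is.na(W))
  callRate <- 1 - nMiss / n
  n1 <- colSums(W == 1L, na.rm = TRUE)
  n2 <- colSums(W == 2L, na.rm = TRUE)
  n0 <- (n - nMiss) - n1 - n2
  p <- (2 * n2 + n1) / pmax(2 * (n - nMiss), 1)
  maf <- pmin(p, 1 - p)
  hweP <- hweChisqP(n0, n1, n2)

  allMissing <- nMiss == n
  failMaf <- !allMissing & maf < thresholds$mafMin
  failCall <- !allMissing & callRate < thresholds$callRateMin
  failHwe <- !allMissing & hweP < thresholds$hwePMin

  # heterozygosity outliers among variants surviving the earlier filters
  het <- n1 / pmax(n - nMiss, 1)
  pool <- !allMissing & !failMaf & !failCall
  mu <- mean(het[pool]); sdev <- sd(het[pool])
  failHet <- pool & sdev > 0 & abs(het - mu) > thresholds$hetSdMax * sdev

  reason <- rep("pass", ncol(W))
  reason[failHet] <- "heterozygosity"
  reason[failHwe] <- "hwe"
  reason[failCall] <- "call_rate"
  reason[failMaf] <- "maf"
  reason[allMissing] <- "all_missing"
  reason <- factor(reason, levels = c("pass", "all_missing", "maf",
                                      "call_rate", "hwe", "heterozygosity"))
  keep <- reason == "pass"
  counts <- table(reason)[c("maf", "call_rate", "hwe", "heterozygosity",
                            "all_missing")]
  list(keep = as.vector(keep), reason = reason,
       counts = as.vector(counts) |>
         stats::setNames(c("maf", "call_rate", "hwe", "heterozygosity",
                           "all_missing")))
}

#' Remove duplicate samples
#'
#' Flags, for every sample pair whose dosage correlation over mutually
#' non-missing loci reaches `dupCorMax`, the later-indexed sample for
#' removal; deterministic given the input order.  Pairs sharing fewer than
#' 30 non-missing loci are skipped with a warning.
#'
#' @param geno a [GenotypeData-class] object (at least 2 samples)
#' @param thresholds a [qcThresholds()] list
#' @return logical keep mask over samples.
#' @export
removeDuplicateSamples <- function(geno, thresholds = qcThresholds()) {
  W <- dosages(geno)
  n <- nrow(W)
  if (n < 2) stop("removeDuplicateSamples: need at least 2 samples")
  keep <- rep(TRUE, n)
  if (!anyNA(W)) {
    # complete data: one correlation matrix
    Wc <- W[, apply(W, 2, function(x) var(x) > 0), drop = FALSE]
    cc <- suppressWarnings(cor(t(Wc)))
    for (i in seq_len(n - 1)) {
      if (!keep[i]) next
      dup <- which(keep & seq_len(n) > i & !is.na(cc[i, ]) &
                     cc[i, ] >= thresholds$dupCorMax)
      keep[dup] <- FALSE
    }
  } else {
    fewShared <- FALSE
    for (i in seq_len(n - 1)) {
      if (!keep[i]) next
      for (j in seq.int(i + 1, n)) {
        if (!keep[j]) next
        ok <- !is.na(W[i, ]) & !is.na(W[j, ])
        if (sum(ok) < 30) { fewShared <- TRUE; next }
        r <- suppressWarnings(cor(W[i, ok], W[j, ok]))
        if (!is.na(r) && r >= thresholds$dupCorMax) keep[j] <- FALSE
      }
    }
    if (fewShared)
      warning("removeDuplicateSamples: some pairs shared < 30 loci and were skipped")
  }
  keep
}

#' Mean-impute missing dosages
#'
#' Replaces each missing entry by the variant's mean dosage among
#' non-missing samples.  Intended for the post-QC matrix (all-missing
#' variants are removed upstream).  Column means are unchanged.
#'
#' @param geno a [GenotypeData-class] object
#' @return a [GenotypeData-class] object whose dosage matrix is numeric
#'   (imputed means are fractional) and complete.
#' @export
meanImputeMissing <- function(geno) {
  W <- dosages(geno)
  if (!anyNA(W)) return(geno)
  Wn <- matrix(as.numeric(W), nrow(W), ncol(W), dimnames = dimnames(W))
  mu <- colMeans(Wn, na.rm = TRUE)
  idx <- which(is.na(Wn), arr.ind = TRUE)
  Wn[idx] <- mu[idx[, 2]]
  out <- geno
  out@dosages <- Wn
  out
}

#' Apply full variant and sample QC
#'
#' Convenience wrapper: variant filters, duplicate-sample removal, then mean
#' imputation of remaining missing dosages.
#'
#' @param geno a [GenotypeData-class] object
#' @param thresholds a [qcThresholds()] list
#' @return list with `genotypes` (filtered, imputed [GenotypeData-class]),
#'   `variantReport` and `sampleKeep`.
#' @export
applyQc <- function(geno, thresholds = qcThresholds()) {
  vr <- filterVariants(geno, thresholds)
  g2 <- subsetGenotypes(geno, variants = vr$keep)
  sk <- removeDuplicateSamples(g2, thresholds)
  g3 <- subsetGenotypes(g2, samples = sk)
  list(genotypes = meanImputeMissing(g3), variantReport = vr,
       sampleKeep = sk)
}
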