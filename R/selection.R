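# The seven variant-preselection scenarios and LD pruning of the selected
# set.  Scenarios differ in source panel (sequence vs HD), selection rule
# (GWAS-only, all variants in significant RHM windows, or GWAS-significant
# variants within RHM windows) and RHM window size (1 Mbp scan vs 250 kbp
# refinement).

#' Selection scenario definitions
#'
#' Returns the configuration of one of the seven preselection scenarios:
#' \tabular{llll}{
#'   scenario \tab panel \tab rule \tab RHM window \cr
#'   1 \tab seq \tab gwas_only \tab none \cr
#'   2 \tab hd  \tab gwas_only \tab none \cr
#'   3 \tab seq \tab rhm_all_variants \tab scan (1 Mbp) \cr
#'   4 \tab seq \tab rhm_all_variants \tab refined (250 kbp) \cr
#'   5 \tab hd  \tab rhm_all_variants \tab refined (250 kbp) \cr
#'   6 \tab seq \tab gwas_within_rhm \tab refined (250 kbp) \cr
#'   7 \tab hd  \tab gwas_within_rhm \tab refined (250 kbp) \cr
#' }
#'
#' @param id scenario number 1-7
#' @param gwasThreshold,rhmThreshold `-log10(p)` thresholds (default 3)
#' @return a `selectionScenario` list with `id`, `panel`, `rule`,
#'   `rhmWindow` and the thresholds.
#' @export
selectionScenario <- function(id, gwasThreshold = 3, rhmThreshold = 3) {
  stopifnot(id %in% 1:7)
  def <- list(
    list(panel = "seq", rule = "gwas_only", rhmWindow = "none"),
    list(panel = "hd", rule = "gwas_only", rhmWindow = "none"),
    list(panel = "seq", rule = "rhm_all_variants", rhmWindow = "scan"),
    list(panel = "seq", rule = "rhm_all_variants", rhmWindow = "refined"),
    list(panel = "hd", rule = "rhm_all_variants", rhmWindow = "refined"),
    list(panel = "seq", rule = "gwas_within_rhm", rhmWindow = "refined"),
    list(panel = "hd", rule = "gwas_within_rhm", rhmWindow = "refined"))[[id]]
  structure(c(list(id = id), def,
              list(gwasThreshold = gwasThreshold,
                   rhmThreshold = rhmThreshold)),
            class = "selectionScenario")
}

#' Select variants under a scenario
#'
#' Applies the scenario's rule to discovery-subset association results:
#' `gwas_only` keeps all panel variants reaching the GWAS threshold
#' genome-wide; `rhm_all_variants` keeps every panel variant inside RHM
#' windows reaching the RHM threshold (overlapping windows contribute the
#' union of their variants); `gwas_within_rhm` keeps the intersection of the
#' two criteria.  Non-converged RHM windows are never used.
#'
#' @param scenario a [selectionScenario()] object
#' @param gwas [runGwas()] results (computed on the discovery subset)
#' @param rhm [rhmScan()] or [rhmRefine()] window results matching the
#'   scenario's window type (ignored for `gwas_only`)
#' @param geno [GenotypeData-class] providing panel membership
#' @return `data.frame` (the variant set) with `id`, `chrom`, `pos`,
#'   `gwasP` (`NA` under `rhm_all_variants`), `window`; zero rows with a
#'   warning when the selection is empty.
#' @export
selectVariants <- function(scenario, gwas, rhm = NULL, geno) {
  mk <- markerMap(geno)
  onPanel <- mk$id[mk[[scenario$panel]]]

  gwasHit <- gwas$id[!is.na(gwas$neglog10p) &
                       gwas$neglog10p >= scenario$gwasThreshold]
  inWindows <- function() {
    if (is.null(rhm)) stop("selectVariants: scenario requires RHM windows")
    sel <- rhm[!is.na(rhm$neglog10p) &
                 rhm$neglog10p >= scenario$rhmThreshold &
                 rhm$converged, , drop = FALSE]
    hit <- rep(FALSE, nrow(mk))
    win <- rep(NA_integer_, nrow(mk))
    for (i in seq_len(nrow(sel))) {
      j <- mk$chrom == sel$chrom[i] & mk$pos >= sel$startBp[i] &
        mk$pos <= sel$endBp[i]
      win[j & !hit] <- sel$window[i]
      hit <- hit | j
    }
    list(ids = mk$id[hit], window = stats::setNames(win, mk$id))
  }

  if (scenario$rule == "gwas_only") {
    ids <- intersect(gwasHit, onPanel)
    win <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  } else if (scenario$rule == "rhm_all_variants") {
    iw <- inWindows()
    ids <- intersect(iw$ids, onPanel)
    win <- iw$window[ids]
  } else {
    iw <- inWindows()
    ids <- intersect(intersect(gwasHit, iw$ids), onPanel)
    win <- iw$window[ids]
  }
  keep <- match(ids, mk$id)
  gp <- if (scenario$rule == "rhm_all_variants")
    rep(NA_real_, length(ids)) else gwas$p[match(ids, gwas$id)]
  out <- data.frame(id = ids, chrom = mk$chrom[keep], pos = mk$pos[keep],
                    gwasP = gp, window = as.integer(win),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("selectVariants: empty selection for scenario ", scenario$id,
            " (downstream model degenerates to the 50k-only GBLUP)")
  out
}

#' LD-prune a selected variant set
#'
#' Within each sliding window (study default 100 kbp shifted by 50 kbp), any
#' variant pair with squared dosage correlation at or above `r2Max` loses
#' its less significant member (larger GWAS p; ties broken by keeping the
#' smaller bp position).  When GWAS p-values are unavailable for the set,
#' pruning keeps the earlier position.  After the pass no surviving
#' within-window pair reaches `r2Max`.
#'
#' @param set variant set from [selectVariants()]
#' @param geno [GenotypeData-class] with complete dosages for the set
#' @param r2Max squared-correlation ceiling (study default 0.95)
#' @param windowBp window size in bp (study default 100000)
#' @param stepBp window shift in bp (study default 50000)
#' @return the pruned set with a logical `kept` audit attached as attribute
#'   `"audit"` (`data.frame`: id, kept, reason).
#' @export
ldPrune <- function(set, geno, r2Max = 0.95, windowBp = 100000,
                    stepBp = 50000) {
  if (nrow(set) == 0) return(set)
  W <- dosages(subsetGenotypes(geno, variants = set$id))
  if (anyNA(W)) stop("ldPrune: dosages must be complete for the set")
  # smaller priority value wins; variants without a GWAS p fall back to
  # position order (earlier kept)
  prio <- set$gwasP
  if (all(is.na(prio))) {
    prio <- order(order(set$chrom, set$pos))
  } else {
    prio[is.na(prio)] <- 2  # worse than any p-value
  }
  keep <- rep(TRUE, nrow(set))
  reason <- rep("kept", nrow(set))
  for (ch in unique(set$chrom)) {
    idx <- which(set$chrom == ch)
    maxPos <- max(set$pos[idx])
    wins <- slidingWindows(maxPos, windowBp, stepBp, unit = "bp")
    for (r in seq_len(nrow(wins))) {
      repeat {
        inw <- idx[keep[idx] & set$pos[idx] >= wins$start[r] &
                     set$pos[idx] <= wins$end[r]]
        if (length(inw) < 2) break
        cc <- suppressWarnings(cor(W[, inw, drop = FALSE]))^2
        cc[!is.finite(cc)] <- 0
        diag(cc) <- 0
        top <- which(cc >= r2Max, arr.ind = TRUE)
        if (nrow(top) == 0) break
        i1 <- inw[top[1, 1]]; i2 <- inw[top[1, 2]]
        drop <- if (prio[i1] > prio[i2]) i1
        else if (prio[i2] > prio[i1]) i2
        else if (set$pos[i1] > set$pos[i2]) i1 else i2
        keep[drop] <- FALSE
        reason[drop] <- sprintf("r2>=%.2f with %s", r2Max,
                                set$id[if (drop == i1) i2 else i1])
      }
    }
  }
  out <- set[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- data.frame(id = set$id, kept = keep,
                                   reason = reason,
                                   stringsAsFactors = FALSE)
  out
}

#' Scenario summary table
#'
#' One row per evaluated scenario: selection rule, selected-variant count
#' after pruning, cross-validation accuracy and dispersion slope with their
#' standard errors across replicates.
#'
#' @param results named list; each element holds `scenario` (a
#'   [selectionScenario()]), `set` (pruned variant set) and `cv` (an
#'   [evaluateCv()] report); elements without a `scenario` (panel baselines)
#'   report their name as the criterion
#' @return `data.frame` with columns `scenario`, `criteria`, `nSelected`,
#'   `accuracy`, `accuracySe`, `slope`, `slopeSe`.
#' @export
scenarioTable <- function(results) {
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    crit <- if (!is.null(x$scenario))
      paste0("50k + top_", sub("_", ".", x$scenario$rule), ".",
             x$scenario$panel)
    else nm
    data.frame(scenario = nm, criteria = crit,
               nSelected = if (!is.null(x$set)) nrow(x$set) else NA_integer_,
               accuracy = x$cv$accuracy, accuracySe = x$cv$accuracySe,
               slope = x$cv$slope, slopeSe = x$cv$slopeSe,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
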