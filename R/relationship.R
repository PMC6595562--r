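# Pedigree numerator relationship matrix and genomic relationship matrices.

#' Pedigree numerator relationship matrix (A)
#'
#' Tabular (recursive) method over the full pedigree, then sliced to the
#' requested individuals, so relationships through non-subset ancestors are
#' retained.  Diagonal entries are `1 + F_i` with `F_i` the inbreeding
#' coefficient.
#'
#' @param pedigree `data.frame` with `id`, `sire`, `dam` (`NA` = unknown),
#'   ordered parents before offspring
#' @param subset individual ids to keep (default: all)
#' @return a [RelationshipMatrix-class] with provenance `"pedigree"`.
#' @export
pedigreeA <- function(pedigree, subset = pedigree$id) {
  validatePedigree(pedigree)
  n <- nrow(pedigree)
  s <- match(pedigree$sire, pedigree$id)
  d <- match(pedigree$dam, pedigree$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (!is.na(si) && !is.na(di)) {
      A[i, i] <- 1 + 0.5 * A[si, di]
      if (i > 1) {
        j <- seq_len(i - 1L)
        A[i, j] <- A[j, i] <- 0.5 * (A[si, j] + A[di, j])
      }
    } else if (!is.na(si) || !is.na(di)) {
      pi <- if (is.na(si)) di else si
      A[i, i] <- 1
      if (i > 1) {
        j <- seq_len(i - 1L)
        A[i, j] <- A[j, i] <- 0.5 * A[pi, j]
      }
    } else {
      A[i, i] <- 1
    }
  }
  dimnames(A) <- list(pedigree$id, pedigree$id)
  k <- match(subset, pedigree$id)
  if (anyNA(k)) stop("pedigreeA: subset ids not in pedigree")
  RelationshipMatrix(A[k, k, drop = FALSE], "pedigree", ids = subset)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `K = Zc Zc' / c` with `Zc` the column-centred dosage matrix (centred at
#' `2 p_j`), `c = 2 * sum_j p_j (1 - p_j)` and allele frequencies `p_j`
#' estimated from the analysed individuals.  Monomorphic variants are
#' excluded; dosages must be complete (impute first).  The scaled factor
#' `Z = Zc / sqrt(c)` is kept on the object for low-rank model fitting.
#'
#' @param geno a [GenotypeData-class] object (complete dosages)
#' @param variants variant ids or index to use (default: all)
#' @param samples individual ids to use (default: all)
#' @param provenance provenance tag (default `"panel:custom"`)
#' @return a [RelationshipMatrix-class].
#' @export
grm <- function(geno, variants = NULL, samples = NULL,
                provenance = "panel:custom") {
  g <- subsetGenotypes(geno, samples = samples, variants = variants)
  W <- dosages(g)
  if (anyNA(W)) stop("grm: dosages must be complete; impute missing first")
  if (ncol(W) == 0) stop("grm: empty variant subset")
  p <- colMeans(W) / 2
  polym <- p > 0 & p < 1
  if (!any(polym)) stop("grm: all variants are monomorphic")
  W <- W[, polym, drop = FALSE]
  p <- p[polym]
  cc <- 2 * sum(p * (1 - p))
  Z <- sweep(W, 2, 2 * p) / sqrt(cc)
  K <- tcrossprod(Z)
  RelationshipMatrix(K, provenance, ids = rownames(W),
                     variantIds = colnames(W), factor = Z)
}

#' Regional genomic relationship matrix
#'
#' [grm()] applied to the variants of one genomic window, used by regional
#' heritability mapping.  Windows carrying fewer than `minVariants`
#' polymorphic variants are skipped (returns `NULL` with the reason as an
#' attribute-free message via `warning`-less signalling: callers check for
#' `NULL`).
#'
#' @param geno a [GenotypeData-class] object
#' @param chrom chromosome
#' @param startBp,endBp inclusive bp bounds of the window
#' @param samples individual ids to use (default: all)
#' @param panel marker panel to draw variants from (`"seq"`, `"hd"`,
#'   `"array50k"`)
#' @param minVariants minimum variant count (default 20)
#' @return a [RelationshipMatrix-class], or `NULL` when the window is below
#'   `minVariants`.
#' @export
regionalGrm <- function(geno, chrom, startBp, endBp, samples = NULL,
                        panel = "seq", minVariants = 20) {
  mk <- markerMap(geno)
  sel <- mk$chrom == chrom & mk$pos >= startBp & mk$pos <= endBp & mk[[panel]]
  if (sum(sel) < minVariants) return(NULL)
  grm(geno, variants = mk$id[sel], samples = samples,
      provenance = sprintf("region:%s:%d-%d", chrom, startBp, endBp))
}

#' Check positive semi-definiteness and optionally repair
#'
#' Verifies `min eigenvalue >= -tol * max eigenvalue`; when violated, adds
#' `eps` to the diagonal once.
#'
#' @param rel a [RelationshipMatrix-class]
#' @param tol relative eigenvalue tolerance
#' @param eps diagonal ridge used for repair
#' @return the (possibly repaired) [RelationshipMatrix-class].
#' @export
ensurePsd <- function(rel, tol = 1e-8, eps = 1e-6) {
  ev <- eigen(rel@K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev))) {
    message("ensurePsd: adding ridge of ", eps, " to the diagonal")
    rel@K <- rel@K + diag(eps, nrow(rel@K))
  }
  rel
}
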