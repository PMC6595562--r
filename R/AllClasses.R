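#' @import methods
#' @importFrom stats var cor sd rnorm runif rbinom rpois qnorm pchisq qchisq
#'   optimize optim lm residuals model.matrix coef complete.cases pnorm
#'   setNames ks.test binom.test
#' @importFrom utils read.table write.table head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Genotype dosages with a marker map
#'
#' Container for an individuals-by-variants dosage matrix (0/1/2, `NA` for
#' missing) and its marker map.  The map records, per variant, the chromosome,
#' 1-based bp position and membership flags for the three nested marker
#' panels: every variant belongs to the sequence (`seq`) panel, a subset is on
#' the high-density (`hd`) array and a subset of that on the medium-density
#' (`array50k`) array, mirroring how lower-density arrays tag a sequenced
#' genome.
#'
#' @slot dosages integer matrix, individuals in rows (rownames = ids),
#'   variants in columns (colnames = variant ids); entries 0, 1, 2 or `NA`.
#' @slot markers `data.frame` with columns `id`, `chrom`, `pos`, `seq`,
#'   `hd`, `array50k` and optionally `freq` (simulated founder frequency).
#'
#' @aliases GenotypeData-class
#' @export
setClass("GenotypeData",
  representation(dosages = "matrix", markers = "data.frame"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  d <- object@dosages
  mk <- object@markers
  if (ncol(d) != nrow(mk))
    msg <- c(msg, "number of dosage columns must equal number of marker rows")
  need <- c("id", "chrom", "pos", "seq", "hd", "array50k")
  if (!all(need %in% names(mk)))
    msg <- c(msg, paste("marker map must have columns:",
                        paste(need, collapse = ", ")))
  if (length(msg) == 0L) {
    # raw dosages are 0/1/2; mean-imputed matrices may hold fractional values
    bad <- d[!is.na(d) & (d < 0 | d > 2)]
    if (length(bad)) msg <- c(msg, "dosages must lie in [0, 2] or be NA")
    if (any(mk$array50k & !mk$hd) || any(mk$hd & !mk$seq))
      msg <- c(msg, "panel flags must be nested: array50k within hd within seq")
    for (ch in unique(mk$chrom)) {
      p <- mk$pos[mk$chrom == ch]
      if (any(diff(p) <= 0)) {
        msg <- c(msg, sprintf("positions not strictly increasing on chromosome %s", ch))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosages individuals-by-variants matrix of 0/1/2 dosages (`NA` =
#'   missing); rownames are individual ids, colnames variant ids.
#' @param markers marker map `data.frame` (see [GenotypeData-class]).
#' @return a [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosages, markers) {
  if (is.double(dosages) &&
      all(dosages == round(dosages), na.rm = TRUE))
    storage.mode(dosages) <- "integer"
  if (is.null(colnames(dosages))) colnames(dosages) <- markers$id
  markers$id <- as.character(markers$id)
  new("GenotypeData", dosages = dosages, markers = markers)
}

#' @describeIn GenotypeData dosage matrix accessor
#' @param x a `GenotypeData` object
#' @export
dosages <- function(x) x@dosages

#' @describeIn GenotypeData marker map accessor
#' @export
markerMap <- function(x) x@markers

#' @describeIn GenotypeData number of individuals
#' @export
nSamples <- function(x) nrow(x@dosages)

#' @describeIn GenotypeData number of variants
#' @export
nVariants <- function(x) ncol(x@dosages)

#' Variant ids belonging to a marker panel
#'
#' @param x a [GenotypeData-class] object
#' @param panel one of `"seq"`, `"hd"`, `"array50k"`
#' @return character vector of variant ids on the panel.
#' @export
panelVariants <- function(x, panel = c("seq", "hd", "array50k")) {
  panel <- match.arg(panel)
  x@markers$id[x@markers[[panel]]]
}

#' Subset a GenotypeData object
#'
#' @param x a [GenotypeData-class] object
#' @param samples individual ids (or logical/integer index) to keep
#' @param variants variant ids (or logical/integer index) to keep
#' @return a [GenotypeData-class] object.
#' @export
subsetGenotypes <- function(x, samples = NULL, variants = NULL) {
  d <- x@dosages
  mk <- x@markers
  if (!is.null(variants)) {
    j <- if (is.character(variants)) match(variants, mk$id) else
      seq_len(nrow(mk))[variants]
    if (anyNA(j)) stop("unknown variant ids in subset")
    j <- sort(j)
    d <- d[, j, drop = FALSE]
    mk <- mk[j, , drop = FALSE]
    rownames(mk) <- NULL
  }
  if (!is.null(samples)) {
    i <- if (is.character(samples)) match(samples, rownames(d)) else
      seq_len(nrow(d))[samples]
    if (anyNA(i)) stop("unknown sample ids in subset")
    d <- d[i, , drop = FALSE]
  }
  new("GenotypeData", dosages = d, markers = mk)
}

setMethod("show", "GenotypeData", function(object) {
  mk <- object@markers
  cat("GenotypeData:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "variants\n")
  cat("  chromosomes:", length(unique(mk$chrom)),
      " panels: seq =", sum(mk$seq), " hd =", sum(mk$hd),
      " 50k =", sum(mk$array50k), "\n")
  miss <- mean(is.na(object@dosages))
  cat(sprintf("  missing rate: %.4f\n", miss))
})

#' Relationship matrix with provenance
#'
#' Symmetric positive semi-definite matrix of additive relationships among
#' individuals, tagged with how it was built: `"pedigree"` for the numerator
#' relationship matrix A, `"panel:<name>"` for a genome-wide GRM,
#' `"region:<chrom>:<start>-<end>"` for a regional GRM, `"top:<scenario>"`
#' for a GRM on preselected variants.  When built from markers the scaled,
#' centred dosage factor Z (with K = ZZ') may be kept to enable low-rank
#' model fitting.
#'
#' @slot K symmetric numeric matrix, dimnames = individual ids.
#' @slot provenance character tag.
#' @slot ids ordered individual ids.
#' @slot variantIds variant ids used (empty for pedigree).
#' @slot factor optional matrix Z with `K = Z %*% t(Z)`, or `NULL`.
#'
#' @aliases RelationshipMatrix-class
#' @export
setClass("RelationshipMatrix",
  representation(K = "matrix", provenance = "character", ids = "character",
                 variantIds = "character", factor = "matrixOrNULL"))

setValidity("RelationshipMatrix", function(object) {
  msg <- character()
  K <- object@K
  if (nrow(K) != ncol(K)) msg <- c(msg, "matrix must be square")
  else {
    if (length(object@ids) != nrow(K))
      msg <- c(msg, "ids must match matrix dimension")
    if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
      msg <- c(msg, "matrix must be symmetric")
    if (any(diag(K) < -1e-8)) msg <- c(msg, "diagonal must be nonnegative")
    if (identical(object@provenance, "pedigree") && any(diag(K) < 1 - 1e-8))
      msg <- c(msg, "pedigree A diagonal must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

RelationshipMatrix <- function(K, provenance, ids = rownames(K),
                               variantIds = character(), factor = NULL) {
  K <- (K + t(K)) / 2
  dimnames(K) <- list(ids, ids)
  new("RelationshipMatrix", K = K, provenance = provenance,
      ids = as.character(ids), variantIds = as.character(variantIds),
      factor = factor)
}

#' @describeIn RelationshipMatrix matrix accessor
#' @param x a `RelationshipMatrix`
#' @export
relMatrix <- function(x) x@K

#' @describeIn RelationshipMatrix provenance tag accessor
#' @export
provenance <- function(x) x@provenance

#' @describeIn RelationshipMatrix individual id accessor
#' @export
relIds <- function(x) x@ids

#' Restrict a relationship matrix to a set of individuals
#'
#' @param x a [RelationshipMatrix-class]
#' @param ids individual ids to keep, in the requested order
#' @return a [RelationshipMatrix-class] over `ids`.
#' @export
subsetRel <- function(x, ids) {
  i <- match(ids, x@ids)
  if (anyNA(i)) stop("unknown individual ids in relationship matrix subset")
  f <- if (!is.null(x@factor)) x@factor[i, , drop = FALSE] else NULL
  RelationshipMatrix(x@K[i, i, drop = FALSE], x@provenance, ids = x@ids[i],
                     variantIds = x@variantIds, factor = f)
}

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix [", object@provenance, "]: ",
      nrow(object@K), " x ", ncol(object@K), "\n", sep = "")
  cat(sprintf("  mean diagonal: %.4f", mean(diag(object@K))))
  if (length(object@variantIds))
    cat("  (", length(object@variantIds), " variants)", sep = "")
  cat("\n")
})
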