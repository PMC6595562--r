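# PLINK 1.9 BED/BIM/FAM input and output, plus TSV helpers for pedigree and
# phenotype tables.  BED is SNP-major, 2 bits per genotype: 00 = homozygous
# first allele (dosage 0), 01 = missing, 10 = heterozygous (1), 11 =
# homozygous second allele (2); samples packed 4 per byte, lowest bits
# first.

#' Read a PLINK BED/BIM/FAM fileset
#'
#' @param prefix path prefix (reads `<prefix>.bed/.bim/.fam`)
#' @return a [GenotypeData-class]; the panel flags default to
#'   sequence-panel membership only (BIM carries no panel annotation).
#' @export
readPlink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                    stringsAsFactors = FALSE)
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  bedPath <- paste0(prefix, ".bed")
  raw <- readBin(bedPath, "raw", n = file.size(bedPath))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("readPlink: bad BED magic bytes in ", bedPath)
  if (raw[3] != as.raw(0x01))
    stop("readPlink: BED is not in SNP-major mode")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3 != bpv * m)
    stop("readPlink: truncated BED block: expected ", bpv * m,
         " genotype bytes, found ", length(raw) - 3,
         " (offset ", length(raw), ")")
  bytes <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  # genotype code lookup per 2-bit value
  dosageOf <- c(0L, NA_integer_, 1L, 2L)
  D <- matrix(NA_integer_, n, m)
  for (s in 0:3) {
    rows <- seq.int(s + 1L, n, by = 4L)
    if (length(rows) == 0) next
    byteRows <- ceiling(rows / 4)
    code <- bitwAnd(bitwShiftR(bytes[byteRows, , drop = FALSE], 2L * s), 3L)
    D[rows, ] <- dosageOf[code + 1L]
  }
  rownames(D) <- make.unique(as.character(fam[[2]]))
  markers <- data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                        seq = TRUE, hd = FALSE, array50k = FALSE,
                        stringsAsFactors = FALSE)
  GenotypeData(D, markers)
}

#' Write a PLINK BED/BIM/FAM fileset
#'
#' @param geno a [GenotypeData-class] (integer dosages; fractional imputed
#'   dosages cannot be represented and raise an error)
#' @param prefix output path prefix
#' @param pedigree optional pedigree supplying sire/dam/sex for the FAM file
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(geno, prefix, pedigree = NULL) {
  W <- dosages(geno)
  if (is.double(W) && any(W != round(W), na.rm = TRUE))
    stop("writePlink: fractional dosages cannot be stored in BED")
  mk <- markerMap(geno)
  n <- nrow(W)
  m <- ncol(W)
  ids <- rownames(W)
  codeOf <- c(0L, 2L, 3L)  # dosage 0,1,2 -> 2-bit code; missing -> 1
  bpv <- ceiling(n / 4)
  pad <- bpv * 4
  out <- raw(3 + bpv * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  codes <- matrix(1L, pad, m)
  known <- !is.na(W)
  codes[seq_len(n), ][known] <- codeOf[W[known] + 1L]
  if (pad > n) codes[seq.int(n + 1, pad), ] <- 0L  # padding bits
  packed <- codes[seq.int(1, pad, 4), , drop = FALSE] +
    bitwShiftL(codes[seq.int(2, pad, 4), , drop = FALSE], 2L) +
    bitwShiftL(codes[seq.int(3, pad, 4), , drop = FALSE], 4L) +
    bitwShiftL(codes[seq.int(4, pad, 4), , drop = FALSE], 6L)
  out[-(1:3)] <- as.raw(packed)
  writeBin(out, paste0(prefix, ".bed"))
  write.table(data.frame(mk$chrom, mk$id, 0, mk$pos, "A", "B"),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = "F0", iid = ids, pat = "0", mat = "0", sex = 0,
                    phe = -9, stringsAsFactors = FALSE)
  if (!is.null(pedigree)) {
    i <- match(ids, pedigree$id)
    fam$pat <- ifelse(is.na(pedigree$sire[i]), "0", pedigree$sire[i])
    fam$mat <- ifelse(is.na(pedigree$dam[i]), "0", pedigree$dam[i])
    fam$sex <- ifelse(pedigree$sex[i] == "M", 1, 2)
  }
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write or read the pedigree / phenotype tables as TSV
#'
#' @param x pedigree or phenotype `data.frame`
#' @param path file path
#' @return `path` (write) or the `data.frame` (read).
#' @export
writeTableTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTableTsv
#' @export
readTableTsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
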