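# Shared simulated populations, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, maker) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- maker()
  .fixtureCache[[name]]
}

# small multi-breed half-sib population for unit tests
tinyPop <- function() cachedFixture("tiny", function() {
  cfg <- smallSimConfig(nSires = 30, offspringPerSire = 8, nChromosomes = 2,
                        nSeqVariantsPerChrom = 800, seed = 42)
  pop <- simulatePopulation(cfg)
  pop$config <- cfg
  pop$final <- pop$pedigree[pop$pedigree$generation ==
                              max(pop$pedigree$generation), ]
  pop$A <- pedigreeA(pop$pedigree, subset = pop$final$id)
  pop$ystar <- adjustPhenotypes(pop$phenotypes)
  pop
})

# hand-built genotype container
makeGeno <- function(dosages, chrom = NULL, pos = NULL, hd = NULL,
                     k50 = NULL) {
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  if (is.null(hd)) hd <- rep(TRUE, m)
  if (is.null(k50)) k50 <- hd
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("s%03d", seq_len(nrow(dosages)))
  GenotypeData(dosages,
               data.frame(id = sprintf("v%04d", seq_len(m)), chrom = chrom,
                          pos = pos, seq = TRUE, hd = hd, array50k = k50,
                          stringsAsFactors = FALSE))
}
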