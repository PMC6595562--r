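#' Simulation configuration
#'
#' Parameters of the synthetic multi-breed half-sib population.  Population
#' defaults mirror a large industry resource flock: 612 sires each with about
#' 18 recorded half-sib offspring (one offspring per dam), 26 autosomes, a
#' moderately heritable trait (h2 = 0.20) of which five QTL regions jointly
#' explain one tenth (qtl_h2 = 0.02), and fixed effects for age, dam age,
#' sex, rearing-by-birth type, contemporary group and breed proportions.
#' Marker counts are desk-scale: density is configurable and the three panels
#' are nested (50k within HD within sequence).
#'
#' @param nBreeds number of founder breeds
#' @param breedFst breed differentiation (Balding-Nichols F), in `[0, 1)`
#' @param nSires number of sires of the final (phenotyped) generation
#' @param offspringPerSire half-sib family size (one offspring per dam)
#' @param nGenerations total generations including founders; `1` gives
#'   founders only
#' @param nChromosomes number of autosomes
#' @param chromLengthBp chromosome length in bp (1 cM per Mbp)
#' @param nSeqVariantsPerChrom sequence-panel variants per chromosome
#' @param hdFraction fraction of sequence variants also on the HD panel
#' @param array50kFraction fraction also on the 50k panel (subset of HD)
#' @param nQtlRegions number of causal regions
#' @param qtlH2 phenotypic variance fraction jointly explained by the causal
#'   regions
#' @param totalH2 total narrow-sense heritability (polygenic share is
#'   `totalH2 - qtlH2`)
#' @param qtlRegionBp causal-region width in bp
#' @param nCausalPerRegion causal variants per region (sequence-only variants
#'   unless `causalOnArrays = TRUE`)
#' @param causalOnArrays if `FALSE` (default) causal variants are drawn from
#'   variants absent from the HD/50k panels, so arrays tag causals only
#'   through LD
#' @param ldDecayBp distance at which founder haplotype correlation decays to
#'   1/e (first-order autoregressive latent model)
#' @param missingRate genotype missing rate applied to the emitted dosages
#' @param cgBlock contemporary-group (site x year x management) block size
#' @param seed root seed for all simulation substreams
#' @return a `simConfig` list (class `"simConfig"`).
#' @seealso [smallSimConfig()] for a desk-scale preset
#' @export
simConfig <- function(nBreeds = 4, breedFst = 0.10,
                      nSires = 612, offspringPerSire = 18,
                      nGenerations = 2,
                      nChromosomes = 26, chromLengthBp = 1e8,
                      nSeqVariantsPerChrom = 2000,
                      hdFraction = 0.40, array50kFraction = 0.12,
                      nQtlRegions = 5, qtlH2 = 0.02, totalH2 = 0.20,
                      qtlRegionBp = 250000, nCausalPerRegion = 8,
                      causalOnArrays = FALSE,
                      ldDecayBp = 5e4, missingRate = 0,
                      cgBlock = 50, seed = 1L) {
  cfg <- list(nBreeds = as.integer(nBreeds), breedFst = breedFst,
              nSires = as.integer(nSires),
              offspringPerSire = as.integer(offspringPerSire),
              nGenerations = as.integer(nGenerations),
              nChromosomes = as.integer(nChromosomes),
              chromLengthBp = chromLengthBp,
              nSeqVariantsPerChrom = as.integer(nSeqVariantsPerChrom),
              hdFraction = hdFraction, array50kFraction = array50kFraction,
              nQtlRegions = as.integer(nQtlRegions),
              qtlH2 = qtlH2, totalH2 = totalH2,
              qtlRegionBp = qtlRegionBp,
              nCausalPerRegion = as.integer(nCausalPerRegion),
              causalOnArrays = isTRUE(causalOnArrays),
              ldDecayBp = ldDecayBp, missingRate = missingRate,
              cgBlock = as.integer(cgBlock), seed = as.integer(seed))
  validateSimConfig(cfg)
  class(cfg) <- "simConfig"
  cfg
}

#' Desk-scale simulation preset
#'
#' A small population (100 sires, 15 offspring each, 5 chromosomes of 20 Mbp
#' with 4000 sequence variants each) with the same genetic architecture as
#' the full-scale default; used throughout examples and tests.
#'
#' @param ... overrides passed on to [simConfig()]
#' @return a `simConfig` object.
#' @export
smallSimConfig <- function(...) {
  args <- list(nSires = 100, offspringPerSire = 15,
               nChromosomes = 5, chromLengthBp = 2e7,
               nSeqVariantsPerChrom = 4000)
  over <- list(...)
  args[names(over)] <- over
  do.call(simConfig, args)
}

validateSimConfig <- function(cfg) {
  with(cfg, {
    if (nBreeds < 1 || nSires < 1 || offspringPerSire < 1 ||
        nGenerations < 1 || nChromosomes < 1 || nSeqVariantsPerChrom < 1)
      stop("simConfig: counts must be positive", call. = FALSE)
    if (breedFst < 0 || breedFst >= 1)
      stop("simConfig: breedFst must be in [0, 1)", call. = FALSE)
    if (hdFraction <= 0 || hdFraction > 1 ||
        array50kFraction <= 0 || array50kFraction > 1)
      stop("simConfig: panel fractions must be in (0, 1]", call. = FALSE)
    if (array50kFraction > hdFraction)
      stop("simConfig: the 50k panel must nest inside the HD panel",
           call. = FALSE)
    if (qtlH2 < 0 || totalH2 > 1 || qtlH2 > totalH2)
      stop("simConfig: need 0 <= qtlH2 <= totalH2 <= 1", call. = FALSE)
    if (missingRate < 0 || missingRate >= 1)
      stop("simConfig: missingRate must be in [0, 1)", call. = FALSE)
  })
  invisible(cfg)
}
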