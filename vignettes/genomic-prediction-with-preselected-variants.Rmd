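---
title: "Regional heritability mapping and genomic prediction with preselected sequence variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional heritability mapping and genomic prediction with preselected sequence variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wecmap)
```

## The problem

Worm egg count (WEC) is the standard measurement of gastrointestinal
parasite resistance in sheep. It is moderately heritable (around
h² = 0.20 in large multi-breed resource populations), expensive to record,
and its genetic architecture is polygenic: the handful of detectable QTL
regions jointly explain only about a tenth of the heritability. For such
traits, genomic prediction from a standard 50k SNP array gives modest
accuracy, and simply switching to denser panels (HD arrays, whole-genome
sequence) helps only marginally, because the extra variants are mostly in
weak linkage disequilibrium (LD) with the causal mutations and dilute the
signal.

`wecmap` implements the analysis strategy that does help: map QTL regions
in an independent *discovery* subset — with single-variant GWAS and with
regional heritability mapping (RHM) — select sequence variants from the
detected regions, and fit those variants as a *second* genomic relationship
matrix (GRM) alongside the ordinary array GRM in a two-component GBLUP.
The second component lets the selected variants carry a larger per-variant
variance, which is exactly what preselection is for.

## Models

All models operate on adjusted phenotypes `y*`, the OLS residuals of the
trait on its fixed effects (age at recording, dam age, sex,
rearing-by-birth type, contemporary group, and breed proportions fitted as
covariates with one column dropped against the sum-to-one constraint).

**GWAS (single-variant mixed model).**
`y* = 1μ + W_i g_i + Za + e` with `a ~ N(0, A σ²_a)`, `A` the pedigree
numerator relationship matrix. Each variant is tested by a Wald test of
`g_i`. The default *fast* mode estimates the null-model components once and
tests every variant by GLS at that fixed covariance; *exact* mode
re-estimates the components per variant. The two agree closely in ranking
and are both provided because the exact mode is the fidelity reference
while the fast mode makes sequence-scale scans affordable.

Both GWAS and RHM accept the fixed-effect design directly (`covariates=`),
fitting it inside the mixed model instead of working on pre-adjusted
residuals. The two-step shortcut is the workflow convention and remains
the pipeline default, but it is measurably conservative in finite samples:
the adjustment projects out ~p fixed-effect dimensions, and because
contemporary-group levels grow with n the deflation (genomic control
λ ≈ 1 − p/n ≈ 0.95 at desk sizes) does not vanish asymptotically. The
calibration experiments in the test suite therefore use the one-step form,
which is exactly calibrated; analyses chasing borderline signals should
prefer it too.

**RHM (regional heritability mapping).** For a sliding window `i`,

* full model: `y* = 1μ + Z_i u_i + Za + e`, `u_i ~ N(0, GRM_i σ²_u)`
* base model: `y* = 1μ + Za + e`

compared by a likelihood-ratio test whose null distribution is the
boundary mixture `0.5 χ²₀ + 0.5 χ²₁` (the tested variance sits on the edge
of its parameter space). The regional heritability is
`h²_u = σ²_u / (σ²_u + σ²_a + σ²_e)`, with `σ²_a` re-estimated under the
full model of that window (the alternative — holding the base-model `σ²_a`
fixed — is a documented choice we did not take). Windows are defined in
variant counts for the main scan and in bp for the refinement pass; both
share one iterator, with 1-based inclusive coordinates throughout.

**Variant selection.** Seven scenarios combine the source panel (sequence
or HD), the rule (all GWAS hits genome-wide; all variants inside
significant RHM windows; GWAS hits inside significant RHM windows) and the
RHM window size (the 1-scan windows or the 250-kbp refined windows). The
threshold is `-log10(p) ≥ 3` for both GWAS and RHM; "≥" rather than ">" is
the documented convention.
Selected sets are LD-pruned (r² ≥ 0.95 within 100-kbp windows shifted by
50 kbp); the pruned pair keeps its more significant member (position order
when no GWAS p-value applies), because the set exists to carry QTL signal —
array-pruning tools usually keep the first-encountered variant instead.

**Two-component GBLUP.** `y* = 1μ + u_top + u_50k + e` with
`u_top ~ N(0, GRM_top σ²_top)` and `u_50k ~ N(0, GRM_50k σ²_50k)`; selected
variants are excluded from `GRM_50k`. GEBV are the sum of the two component
predictions, and `h²_top = σ²_top / (σ²_top + σ²_50k + σ²_e)` measures the
variance the selected set captures. All GRMs are VanRaden method 1 with
observed-sample allele frequencies — the construction is not dictated by
the workflow and this is the standard GBLUP convention.

**Evaluation.** The phenotyped population is split (whole sire families,
breed-stratified) into a QTL-discovery subset and a training/validation
subset in the proportion 6431 : 4500. Prediction is evaluated by tenfold
sire-family cross-validation, replicated ten times: accuracy is
`cor(GEBV, y*)/√h²` in the validation families and the dispersion slope is
the regression of `y*` on GEBV. Keeping whole half-sib families together
prevents within-family information from leaking between training and
validation. The `h²` in the denominator is estimated once on all phenotyped
animals with the pedigree kernel; on large real datasets pedigree- and
sequence-GRM estimates of total h² typically coincide, but at
desk-scale marker counts a marker GRM is severely attenuated for a
pedigree-simulated polygenic term (see below), so the pedigree estimate is
the right default here and the kernel is a function argument.

## REML engine

Variance components are estimated by restricted maximum likelihood with
components constrained nonnegative; a component estimated at exactly zero
is a legitimate boundary outcome and is what gives the LRT its point mass.
Three routes maximise one and the same restricted likelihood (they are
cross-checked against each other and against a grid-search oracle in the
test suite):

* **one kernel** — eigendecompose the kernel once and profile the
  likelihood in the heritability ratio (Brent search plus an explicit
  boundary candidate at zero);
* **dense + low-rank** — when a model is "pedigree (or panel GRM) plus a
  marker-factor kernel `K = ZZ'` with few columns", rotation by the dense
  kernel's eigenvectors plus the Woodbury identity reduce every likelihood
  evaluation to `O(n q²)`; the optimum is found by bounded quasi-Newton on
  the raw variance scale (lower bounds at zero). This is the RHM window
  case, and it is what makes a scan of hundreds of windows affordable on
  one CPU;
* **general** — average-information REML with 3 EM burn-in iterations,
  step-halving, and pinning of a component at zero after two consecutive
  negative updates (the pinned component leaves the AI system). Converged
  when the restricted log-likelihood changes by less than 1e-6, with a cap
  of 100 iterations; non-converged fits are flagged and RHM windows that
  carry the flag are reported but never selected.

Standard errors come from the inverse average-information matrix at the
optimum, and the delta method gives the SE of `h²_top`.

## The synthetic study population

No public dataset of this design exists to test against, so the package
ships a generator whose defaults mirror a full-scale resource-flock
study: 612 sires with ~18
recorded half-sib offspring each (one offspring per dam), 26 autosomes,
multi-breed founders (Balding–Nichols differentiation, F_ST = 0.10),
h² = 0.20 of which five QTL regions jointly explain 0.02, and the fixed
effects listed above. Marker density is the one deliberately desk-scale
ingredient: real sequence implies tens of millions of variants, which is
neither simulable nor needed to exercise the statistics; `smallSimConfig()`
(100 sires, 5 chromosomes of 20 Mbp with 4000 sequence variants each, one
variant per 5 kbp) is the preset used in examples and tests.

Mechanics and the reasoning behind them:

* **Founder LD** is induced by thresholding a latent first-order
  autoregressive Gaussian process along the chromosome (decay length
  50 kbp). This is the cheapest mechanism that makes nearby variants tag
  each other realistically, so that array panels tag — imperfectly — the
  sequence-only causal variants. Panel flags are nested (50k ⊂ HD ⊂ seq)
  by construction.
* **Meiosis** drops haplotypes through the pedigree with crossovers from a
  Haldane map at 1 cM/Mbp.
* **Causal variants** are drawn from sequence-only (non-array) variants,
  clustered in `nQtlRegions` regions, and their joint effect is rescaled so
  the realized causal variance is exactly `qtlH2` — which is why recovery
  experiments can meaningfully centre on the target value.
* **The polygenic term is pedigree-based** (founder values iid, offspring
  values from parent means plus Mendelian-sampling noise). A consequence
  worth stating plainly: a marker GRM carries *no* information about the
  Mendelian-sampling part of such a term, so marker-based REML estimates of
  h² are attenuated and cross-family marker GBLUP of the polygenic part is
  near-useless at desk marker counts. This is a property of the simulated
  world, not a bug: it reproduces, in exaggerated form, the real situation
  in which array variants sit far from causal variants. Tests that need an
  unattenuated h² therefore use the pedigree kernel, and the prediction
  experiments derive their signal from the planted causal regions, which
  *are* marker-linked.
* **Contemporary groups** (site × year × management blocks of 50, effects
  `N(0, 0.5 σ²_e)`) are assigned by random permutation, spreading each sire
  family across many groups. Industry resource flocks do this deliberately
  to keep genetic links across management units; the alternative
  (family-nested groups) would let the fixed-effect adjustment absorb most
  between-family genetic variance.
* **The WEC-like trait is Gaussian.** The source never states a
  transformation for the raw counts, so no count-distribution layer is
  added; the trait should be read as already transformed. This is flagged
  rather than guessed.

What the generator does **not** emulate: coalescent-realistic allele
frequency spectra, mutation, selection, genotyping or imputation error,
and X/Y chromosomes. Passing tests on this synthetic world therefore show
that the *statistics* behave as designed — calibrated null distributions,
unbiased recovery of planted parameters, correct orderings — not that any
particular accuracy value transfers to real sheep data.

## Problem sizes and experiment design

The validation experiments run at sizes a single CPU handles comfortably;
each choice is a design decision of this package:

* Oracle equivalences (GLS-GWAS, pedigree-BLUP) run at n = 100 and n = 50,
  where explicit-inverse oracles are exact.
* Null calibration uses a 10-chromosome, 10,000-variant map with one
  variant per 100 kbp — twice the LD decay length, so the 10,000 GWAS
  p-values are nearly independent and a Kolmogorov–Smirnov uniformity test
  is meaningful; the RHM null uses 500 non-overlapping 20-variant windows
  for the same reason.
* Parameter recovery (h² = 0.20; regional h² summing to 0.02; h²_top of
  the causal set) runs at n = 2000 with 50 trait re-simulations on one
  genotyped population: the trait seed is the replicate, which keeps the
  genotype-side computation (pedigree A, GRM eigendecompositions) shared.
* The prediction experiment runs at n = 1500 with 20,000 sequence
  variants, split 59:41 into discovery and training/validation, the same
  proportion as the full-scale default configuration. Because a desk-scale
  discovery set is ~7× smaller than the ~6400 animals of the full-scale
  design, the planted causal variance is scaled up accordingly
  (`qtlH2 = 0.12` over five 250-kbp regions of 20 causal variants each) to
  preserve the detection noncentrality; the RHM scan uses 50-variant
  windows (250 kbp at the preset's density) stepped by half a window.
  With the full-scale per-region variance (0.004) the scan would have
  essentially no power at this n and every selection scenario would return
  noise — the scaled design tests the same directional claim at desk size.

## Numerical choices and degenerate inputs

* GRMs exclude monomorphic variants; an all-monomorphic request is an
  error. A positive-semidefiniteness check (`ensurePsd()`) can add a one-off
  1e-6 ridge, with a message.
* RHM windows below the minimum variant count (default 20) are skipped
  with a reason; the truncated last window of a chromosome is kept if it
  clears the same minimum.
* A variant-selection scenario that selects nothing degrades to the
  single-GRM model with a warning, mirroring how the two-component model
  collapses when `σ²_top` is pinned at zero.
* LD pruning is deterministic given the input order; ties on significance
  break toward the smaller bp position.
* `lrtMixtureP()` treats an LRT below 1e-6 as exactly zero and clamps a
  full-model deficit (optimizer failure) to zero with a warning.
* All randomness flows from one root seed through named substreams
  (`substreamSeed()`), so stages rerun reproducibly in isolation.

## Known limitations

* Single-trait models only; no dominance/epistatic kernels, no single-step
  H-matrix, no Bayesian whole-genome regression alternatives.
* The simulator's LD is stationary along the chromosome and breed
  differentiation acts only on allele frequencies, not on LD phase —
  across-breed tagging is therefore more favourable than in real
  multi-breed data.
* Genotype imputation is out of scope; the generator emits complete nested
  panels instead, and the QC module's mean imputation is a placeholder for
  the missing-data step, not a model of imputation error.
* At desk-scale variant counts the multiple-testing landscape differs from
  sequence reality: a genome-wide `-log10(p) ≥ 3` screen yields tens, not
  tens of thousands, of false positives, so the *penalty* of GWAS-only
  selection relative to GWAS-within-RHM selection is much smaller here
  than at sequence scale. Both preselection strategies reliably beat
  the single-GRM baseline on synthetic data, but the relative ranking of
  the two — which at sequence scale favours GWAS-within-RHM — is close to
  a coin flip at a 20,000-variant genome: restricting to detected RHM
  windows discards the causal content of undetected regions, while the
  GWAS-only set pays almost no false-discovery penalty. Expect that
  particular ordering to reproduce only directionally, and only at
  realistic variant counts.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  sim = smallSimConfig(nSires = 25, offspringPerSire = 8,
                       nChromosomes = 2, nSeqVariantsPerChrom = 1000,
                       qtlH2 = 0.12, nCausalPerRegion = 10, seed = 301),
  k = 3, nReplicates = 1, seed = 301, outDir = "wecmap-out")
res <- runPipeline(cfg)
res$scenarioTable
```

The `scenarioTable` holds one row per marker-panel baseline and per
selection scenario: selected-variant count after pruning, cross-validation
accuracy ± SE and dispersion slope ± SE — the study's summary of what each
marker panel and each preselection rule delivers.
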