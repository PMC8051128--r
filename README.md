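# pooltruth

Construction and verification of pooled multi-cell-line genomic
reference truth sets.

## The problem

Validating an oncology sequencing panel requires a reference sample
with a large number of *known* somatic-like variants at low allele
frequency, plus positions certified to be homozygous reference.
Pooling DNA from ten unrelated cancer cell lines achieves this: each
line's germline variants are diluted to roughly a tenth of their
within-line allele fraction, so a private heterozygous variant appears
near 5% variant allele frequency (VAF) and a private homozygous one
near 10%, with thousands of variants spread over 1–20%. `pooltruth`
implements the computational machinery of that design:

* **Consensus target region (CTR)** — intersection of all enrichment
  kit designs, coding regions and high-confidence benchmark regions,
  minus padded low-complexity intervals (`buildCtr`).
* **Class 1 / Class 2 positives** — per-kit majority voting across
  pipeline-library combinations (VAF ≥ 10% on the same cell line, at
  least half the roster), cross-kit intersection inside the CTR, and
  rescue of COSMIC high-confidence loci outside the CTR supported by
  two WGS callers and two WES kit consensuses
  (`voteClass1Kit`, `buildClass1`, `buildClass2`, `mOfNConsensus`).
* **Known negatives** — a pileup filter cascade (per-library DP ≥ 50,
  per-line merged DP ≥ 125 with reference fraction ≥ 99%, ten-line
  average RF ≥ 99.5%, pooled per-kit removal of DP ≥ 500 & ADP > 2 &
  AF ≥ 0.002, indel-adjacent exclusion) in `callNegatives`.
* **Pool and dilution VAF model** — expected pooled VAF under
  DNA-mass pooling with genome-equivalent weighting
  `g_i = mass_i / ploidy_i`:
  `VAF = Σ g_i·alt_i / Σ g_i·cn_i`, dilution arithmetic for admixture
  samples (1:1, 1:4, 1:24), merged-count VAF estimation with exact
  binomial intervals, mixture-proportion regression and cross-line
  contamination detection (`expectedPoolVaf`, `expectedDilutionVaf`,
  `estimateVaf`, `estimateMixture`, `detectContamination`).
* **ddPCR verification** — Poisson droplet occupancy model
  (`λ = -ln(negative fraction)`), VAF estimation with delta-method
  intervals, chi-square occupancy QC, stratified target selection and
  verdicts against sequencing estimates (`ddpcrVaf`,
  `occupancyConsistency`, `selectTargets`, `verifyAssay`).
* **Synthetic cohort generator** — a seeded ~1 Mb in-silico analog of
  the whole study (ten cancer lines + normal, germline sharing, CNA,
  one tetraploid line, a deliberate 2:1 cross-line contamination,
  replicate libraries, dilutions, ddPCR wells) with ground truth for
  every downstream stage (`generateCohort`, `simulatePileups`,
  `simulateCallsets`, `simulateDdpcrWell`).

See the methods vignette (`vignettes/pooled-truthset-methods.Rmd`) for
the models, assumptions and parameter choices.

## Worked example

```r
library(pooltruth)

## ten equal-mass diploid lines; one carries a private het variant
carrier <- cellLineProfile("L1", 0.1, 2L,
                           genotypeTable("c", 100L, "A", "G", 1L, 2L))
others  <- lapply(2:10, function(i) cellLineProfile(paste0("L", i), 0.1))
pool    <- setNames(c(list(carrier), others), paste0("L", 1:10))
expectedPoolVaf(pool, "c:100:A:G")
#> [1] 0.05

## a 0.5% pool variant after 1:24 dilution into a normal line
expectedDilutionVaf(0.005, 1, 0, dilutionSpec(1, 24))
#> [1] 2e-04

## end-to-end on a synthetic cohort
cfg <- cohortConfig(contigs = c(ctgA = 150000L, ctgB = 100000L),
                    sharedCommon = 60L, sharedRare = 60L,
                    privateHetPerLine = 30L, privateHomPerLine = 10L,
                    somaticPerLine = 10L, somaticTly = 40L)
cohort <- generateCohort(cfg, seed = 11)
res <- runTruthsetPipeline(cohort, seed = 5)
res$truthSet
#> TruthSet: 393 Class 1, 33 Class 2, 0 multi-allelic loci excluded

pc  <- pooledConsensus(cohort, seed = 9)
rep <- confirmPositives(res$truthSet, pc, truePoolVaf(cohort))
rep$fractionConfirmed
#> [1] 1
```

The truth set reports the variants that won the per-kit majority vote
in all three replicated kits inside the CTR (Class 1) plus the
WGS-rescued COSMIC loci outside it (Class 2); the confirmation step
re-detects them in a deep simulated pooled sample and checks each
observed VAF against its expectation.

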