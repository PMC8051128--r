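---
title: "Methods: building and verifying a pooled cell-line reference truth set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and verifying a pooled cell-line reference truth set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooltruth)
```

## The problem

Oncology sequencing panels are validated against reference samples with
known ("truth") variant content. A single tumour/normal pair offers only
a handful of low-frequency variants, so a richer design pools DNA from
many unrelated cancer cell lines: each line's germline variants appear
in the pool at roughly one tenth (for ten lines) of their within-line
allele fraction, producing thousands of known positives between 1% and
20% variant allele frequency (VAF), plus millions of positions that can
be certified homozygous-reference ("known negatives"). `pooltruth`
implements the full computational side of that design: defining the
genomic territory where calls are trustworthy, deriving consensus
positives from many independent calling pipelines, certifying negatives
from pileups, modelling expected VAFs in pools and dilution series,
estimating mixture proportions, and verifying results against a droplet
digital PCR (ddPCR) occupancy model. A seeded synthetic cohort generator
provides ground truth for every stage so the whole pipeline is testable
end to end.

## The pool VAF model

Lines are pooled by DNA *mass*. A tetraploid genome packs fewer genome
copies per nanogram than a diploid one, so line $i$ with mass fraction
$m_i$ and base ploidy $p_i$ contributes genome equivalents
$g_i = m_i / p_i$. With local copy number $c_i$ at a locus and $a_i$
alternative-allele copies, the expected pooled VAF is

$$
\mathrm{VAF} \;=\;
  \frac{\sum_i g_i\, a_i}{\sum_i g_i\, c_i}.
$$

For ten equal-mass diploid lines this yields the two canonical
anchors: a private heterozygous variant lands at 5% and a private
homozygous variant at 10%:

```{r pool-vaf}
carrier <- cellLineProfile("L1", 0.1, 2L,
                           genotypeTable("c", 100L, "A", "G", 1L, 2L))
others <- lapply(2:10, function(i) cellLineProfile(paste0("L", i), 0.1))
pool <- setNames(c(list(carrier), others), paste0("L", 1:10))
expectedPoolVaf(pool, "c:100:A:G")
```

The genome-equivalent weighting is the package's own modelling choice:
it is required to make the 5%/10% anchors and the behaviour of a
tetraploid line in a mass pool mutually coherent.

Diluting the pool into a normal diploid line B with mass fraction
$\alpha = \mathrm{parts_A}/(\mathrm{parts_A + parts_B})$ scales an
A-private variant with relative locus representation $\rho$ as
$(\alpha\rho\,v_A + (1-\alpha) v_B) / (\alpha\rho + 1 - \alpha)$; a
0.5% variant reaches 0.02% in a 1:24 dilution, the regime relevant for
liquid-biopsy panels.

Cross-line contamination is modelled as a mass mixture inside one
line's DNA: a host contaminated at contaminant:host ratio $r$ behaves
as two materials with masses $1/(1+r)$ and $r/(1+r)$. A variant
homozygous in a diploid contaminant at ratio 2:1 therefore shows an
effective allele fraction of $2/3$ in the contaminated sample.

## Consensus target region

Positive calling is restricted to a consensus target region (CTR): the
intersection of every enrichment kit's design region, the coding
regions, and all high-confidence benchmark region sets, minus
low-complexity intervals padded by 5 nt on each side. Intervals are
0-based half-open on disk (BED) and are kept in reduced normal form so
set equality is structural; interval arithmetic is delegated to
`GenomicRanges`. The subtraction is applied last; padding is clamped at
contig starts but not at contig ends (a region set does not know contig
lengths).

## Class 1 and Class 2 positives

Each WES kit is analysed by several pipeline-library combinations
(PLCs). Per kit, a variant wins on a cell line when at least
`ceiling(0.5 * rosterSize)` roster PLCs call it with VAF at or above
10% on that line — so 4 of 8 and 4 of 7 pass while 3 of 7 fails; the
roster is the set of PLCs that actually produced call sets, so an
absent pipeline shrinks the denominator rather than counting as a
no-vote. Per-line winners are pooled (union) across lines, the three
replicated kits' lists are intersected, and the result is filtered to
the CTR: these are Class 1 positives. Class 2 positives rescue COSMIC
high-confidence coding loci *outside* the CTR that are supported on a
single line by two distinct WGS callers and by the WES consensus of two
distinct kits; no per-line VAF floor is applied to Class 2 because the
support rules alone define it. Loci showing distinct alternative
alleles across lines would surface as multi-allelic in the pool; they
are flagged, removed from both classes, and reported separately.
Variant identity everywhere is the normalised key
`chrom:pos:ref:alt` (shared suffix then prefix trimmed, one anchor base
kept for indels); no haplotype-equivalence matching is attempted.

Pooled-sample confirmation mimics deep sequencing of the physical pool:
several somatic callers (one indel-only) are applied and calls with
support from at least 3 of them are kept; the consensus VAF is then
recomputed from merged pileup counts — never averaged from caller
reports — and a truth variant counts as confirmed when the expected
VAF falls inside the exact (Clopper–Pearson) interval of the merged
counts. The interval level is 99.9% by default. A 99% interval — the
obvious first choice — has only ~99% coverage by construction, which
would cap the achievable confirmation rate below the 99.5% the
procedure is expected to reach on honest data; the 99.9% default keeps
the check sharp against real discrepancies (it still rejects VAF shifts
of a few interval widths) without failing ~1% of perfectly consistent
variants.

## Known negatives

Negative positions are certified by a filter cascade over pileup counts
(DP, RDP, ADP per position and library), applied exactly in this
order, with every threshold in `negativeFilterConfig()`:

1. per line: every library must cover the position with DP ≥ 50;
2. per line: library-summed DP ≥ 125 and recalculated reference
   fraction (summed RDP / summed DP) ≥ 99%;
3. across lines: unweighted mean RF ≥ 99.5% (boundary inclusive), over
   positions surviving step 2 in *all* lines;
4. pooled sample, per kit (libraries summed): positions with
   DP ≥ 500 **and** ADP > 2 **and** AF ≥ 0.002 are removed (the three
   conditions are a strict conjunction — the literal reading of the
   published rule);
5. positions adjacent to indel calls are removed. "Adjacent" is
   operationalised as the base immediately left of the anchor, the
   reference span of the indel, and the base immediately right of the
   span; a deletion `chr1:100 ATT>A` removes positions 99–103, an
   insertion `chr1:100 A>ATT` removes 99–101. The convention is a
   package choice (the source rule names only "adjacent positions from
   both ends") and is configurable by supplying a different exclusion
   list.

Because the filters are pure conjunctions, reordering stages 3 and 4
cannot change the result, and positions with zero coverage in any line
never become negatives. The retained table records, per position, the
cross-line average RF and the maximum per-kit pooled observed AF.

A caution on the pooled guarantee: retaining only positions with
ADP ≤ 2 bounds the observed AF by 2/DP, which is 0.25% only when the
per-kit pooled depth reaches ~800×. At the study-like depths simulated
here (three libraries averaging 250×), positions with two error reads
at or below average depth legitimately show observed AF between 0.25%
and ~1%. The cascade's structural guarantee — no retained position
violates the removal rule, and every retained position keeps average
RF ≥ 99.5% — holds on every run; the *numeric* 0.25% bound is a
depth-dependent implication, not a property of the filters.

## The synthetic cohort generator

The generator is the package's study-conditions definition, not a
tuning knob. Defaults:

* genome: three contigs totalling 1 Mb; coding exons (~160 bp every
  450 bp) tile the contigs; four kit designs are the padded exons with
  5% random dropout each; four high-confidence sets are the genome
  minus ~5% random holes; low-complexity intervals (~150/Mb, ~25 bp)
  are excluded with 5 nt padding; ~30% of exons are labelled COSMIC.
  The resulting CTR is roughly a quarter of the genome.
* cohort: ten cancer lines plus a normal line B. Per-line CNA burden
  follows the published cohort description (22–90% of the genome, in
  20–80 kb segments at copy numbers 1–4; the tetraploid line TLY uses
  base ploidy 4 with segments at 2, 3 or 6). Germline sharing uses a
  two-class population spectrum (250 loci at frequency 0.3, 250 at
  0.01; per-line dosage Binomial(2, f)), which reproduces the observed
  phenomenon that homozygous private variants are rare — hence a 5%
  pooled mode with no distinct 10% mode. Each line adds 120 private
  het and 40 private hom germline variants and 40 somatic variants
  (TLY: 240, on one copy, hence within-line VAF 0.25 under ploidy 4).
  1.5% of variants are short indels. BLY is contaminated by TLY at
  1:2 contaminant:host mass.
* sequencing: negative-binomial depth per library (size 12), two
  libraries per line at mean 200×, pooled-sample kits with three
  libraries at mean 250×, per-base error 5e-4 (split 1:2 between the
  alternative allele and other bases so RDP+ADP ≤ DP).
* pipelines: per-PLC step sensitivity curves (≈99.5% at VAF ≥ 10%,
  95% at 5–10%, degrading below), Gaussian VAF noise (sd 0.01), and 2
  false calls per Mb placed uniformly in the kit design. The source
  study does not quantify pipeline behaviour; these values were chosen
  once, a priori, to keep consensus voting non-degenerate and to
  reproduce qualitatively the reported ~95% recovery of the
  contaminant's variants inside the contaminated line.
* ddPCR: reference and alternative molecules Poisson-partitioned
  independently across ≥ 1000 droplets (wells with mean occupancy
  above 10 are rejected as saturated); a per-droplet alt-channel
  misclassification rate (default 5e-5) reproduces the sub-0.1%
  background seen in negative samples, which motivates the 0.1%
  verification floor.

What the generator deliberately does not emulate: read-level artefacts
(homopolymer error motifs, strand bias, mappability), polyclonality
beyond CNA heterogeneity, bait-specific VAF bias, and genome-build
liftover. Passing tests therefore demonstrate the correctness of the
*procedures* under an idealised error model, not the field performance
of any laboratory assay.

## Mixture-proportion regression

Pooled-sample VAFs of private variants are regressed (no intercept) on
the per-line VAF profiles; on copy-number-neutral private variants the
coefficients estimate pool mass fractions, so a 2:1 planted mixture
returns coefficients in ratio 2. The design matrix built from VAFs is
deliberately plain ordinary least squares (optionally non-negative via
`pracma::lsqnonneg`); under heavy structural variation such VAF-based
prediction is intrinsically unstable, so the residual standard
deviation is carried on the `MixtureFit` object rather than hidden.
Contamination screening (`detectContamination`) is the complementary
qualitative check: a contaminated sample's call set contains nearly all
of the contaminant's variants, so pairwise variant-overlap fractions
above 0.90 are flagged.

## ddPCR verification

Each well partitions template molecules into droplets; under Poisson
occupancy the per-allele concentration is recovered from the zero
class, $\lambda = -\ln(\text{negative fraction})$, and
$\mathrm{VAF} = \lambda_\mathrm{alt} / (\lambda_\mathrm{ref} +
\lambda_\mathrm{alt})$ with a delta-method interval from the binomial
uncertainty of the two negative fractions. Occupancy consistency is a
Pearson chi-square on the four-way counts against the
independent-occupancy expectation (1 degree of freedom: four cells,
two estimated margins); honest wells fail at about the chosen alpha,
and wells failing QC are excluded from verdicts. Replicate wells are
combined by summing droplet counts, which preserves the sufficient
statistic, not by averaging VAFs. A verdict is `verified_positive`
when the ddPCR VAF clears the 0.1% background floor in every
expected-positive sample and its interval overlaps the sequencing
interval (interval overlap at 99% is the package's operationalisation
of "within stochastic sampling noise"; the source procedure names no
test), `verified_negative` when all expected-negative samples stay
below the floor, `discordant` otherwise. Target selection for
verification is stratified random sampling with a 30 bp
proximity-exclusion window, deterministic given a seed.

## Problem sizes and numerical choices

Simulations in the test suite use cohorts between ~250 kb (module
tests) and 1 Mb (the negative-locus cascade), chosen so each property
is measured on thousands to hundreds of thousands of positions while a
full run stays in the minutes range on one CPU. Seeds are explicit
everywhere; one master seed fans out deterministically to every
stochastic stage. Boundary semantics follow the published rules:
vote thresholds use `ceiling`, RF and VAF floors are inclusive (≥),
the pooled removal requires ADP strictly greater than 2. Degenerate
inputs are defined rather than accidental: zero-depth groups report a
missing (not zero) VAF estimate, empty region sets intersect to empty,
a saturated ddPCR well (no negative droplets) is an error, and
rank-deficient mixture designs fail with the collinear lines named.

## Known limitations

* Variant matching is exact-key only; representation differences that
  survive minimal normalisation (true left-alignment through repeats,
  MNV splitting/joining) are not resolved.
* The negative cascade is single-build; the published dual-build
  (liftover-intersection) step is out of scope.
* The 0.25% pooled-AF implication holds only at pooled depths ≥ ~800×,
  as discussed above.
* ddPCR wells arrive pre-clustered; fluorescence clustering and manual
  threshold adjustment have no computational analogue here.
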