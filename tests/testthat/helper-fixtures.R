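## Shared fixtures: small seeded cohorts and brute-force oracles.
## Cohorts are generated once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

## Small full-design cohort (10 cancer lines + normal, ~250 kb genome).
smallCohort <- function() {
    if (is.null(.fixtureCache$small)) {
        cfg <- cohortConfig(
            contigs = c(ctgA = 150000L, ctgB = 100000L),
            sharedCommon = 60L, sharedRare = 60L,
            privateHetPerLine = 30L, privateHomPerLine = 10L,
            somaticPerLine = 10L, somaticTly = 40L)
        .fixtureCache$small <- generateCohort(cfg, seed = 11L)
    }
    .fixtureCache$small
}

## Two diploid lines, no CNA, pooled 2:1 by mass (mixture-recovery cases).
twoLineCohort <- function(seed = 7L) {
    key <- paste0("two", seed)
    if (is.null(.fixtureCache[[key]])) {
        cfg <- cohortConfig(
            contigs = c(ctgA = 200000L, ctgB = 150000L),
            lineIds = c("X", "Y"), normalId = "B",
            tetraploidLine = "none",
            cnaFraction = c(X = 0, Y = 0, B = 0),
            sharedCommon = 0L, sharedRare = 0L,
            privateHetPerLine = 150L, privateHomPerLine = 60L,
            somaticPerLine = 0L, somaticTly = 0L, indelFraction = 0,
            contamination = NULL,
            poolMassFractions = c(X = 2 / 3, Y = 1 / 3))
        .fixtureCache[[key]] <- generateCohort(cfg, seed = seed)
    }
    .fixtureCache[[key]]
}

## Perfect-caller profiles: sensitivity 1 everywhere, no noise, no FPs.
perfectProfiles <- function(cohort) {
    profs <- list()
    one <- sensitivityStep(0, 1)
    for (kit in names(cohort@kitRosters))
        for (plc in cohort@kitRosters[[kit]])
            profs[[plc]] <- pipelineProfile(plc, kit, one, fpRate = 0,
                                            vafNoiseSd = 0)
    profs
}

## Oracle: per-base boolean occupancy array for a single-contig RegionSet.
booleanMask <- function(rs, contigLen, chrom = "c") {
    mask <- rep(FALSE, contigLen)
    gr <- regionRanges(rs)
    gr <- gr[as.character(GenomeInfoDb::seqnames(gr)) == chrom]
    for (i in seq_along(gr)) {
        s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
        mask[s:e] <- TRUE
    }
    mask
}

## Random single-contig RegionSet for oracle comparisons.
randomRegionSet <- function(contigLen, n, chrom = "c", name = "rand") {
    start <- sort(sample.int(contigLen - 50L, n))
    len <- sample(5:200, n, replace = TRUE)
    RegionSet(rep(chrom, n), start - 1L, pmin(start - 1L + len, contigLen),
              name = name)
}

## Measured per-variant VAFs of a cohort sample from simulated pileups
## restricted to the variant loci (summed over libraries).
measuredVafs <- function(cohort, sample, meanDepth = 100, nLibs = 2L,
                         seed = 1L) {
    tv <- truePoolVaf(cohort)
    vr <- parseVariantKey(tv$key)
    vreg <- RegionSet(vr$chrom, vr$pos - 1L, vr$pos, "loci")
    p <- simulatePileups(cohort, sample, libraryIds = paste0("L", seq_len(nLibs)),
                         meanDepth = meanDepth, regions = vreg, seed = seed)
    a <- p[, list(DP = sum(DP), ADP = sum(ADP)), by = c("chrom", "pos")]
    a$vaf <- a$ADP / a$DP
    a$key <- tv$key[match(paste(a$chrom, a$pos), paste(vr$chrom, vr$pos))]
    a[, c("key", "vaf"), with = FALSE]
}

## Reference pileup row builder.
pileRow <- function(chrom, pos, lib, dp, rdp, adp) {
    data.table::data.table(chrom = chrom, pos = as.integer(pos),
                           libraryId = lib, DP = as.integer(dp),
                           RDP = as.integer(rdp), ADP = as.integer(adp))
}
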