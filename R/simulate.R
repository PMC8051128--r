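## Sequencing-level simulators: per-library pileups (negative-binomial
## depth, binomial allele sampling with a per-base error rate), noisy
## per-pipeline call sets, dilution-sample pileups, and ddPCR droplet
## wells.

## Effective allele-fraction table for a sample of the cohort.
.sampleAfTable <- function(cohort, sample) {
    if (sample == "A") truePoolVaf(cohort)
    else trueLineVaf(cohort, sample)
}

## Vectorised pileup sampler over a position table with allele fractions.
.samplePileup <- function(posTab, af, libraryIds, meanDepth, dispersion,
                          errorRate) {
    n <- nrow(posTab)
    if (length(meanDepth) == 1L)
        meanDepth <- rep(meanDepth, length(libraryIds))
    out <- vector("list", length(libraryIds))
    pAlt <- af * (1 - errorRate) + (1 - af) * errorRate
    for (j in seq_along(libraryIds)) {
        DP <- if (is.infinite(dispersion)) rep(as.integer(meanDepth[j]), n)
              else stats::rnbinom(n, size = dispersion, mu = meanDepth[j])
        ADP <- stats::rbinom(n, DP, pAlt)
        ODP <- stats::rbinom(n, DP - ADP, errorRate)  # other-allele errors
        out[[j]] <- data.table::data.table(
            chrom = posTab$chrom, pos = posTab$pos,
            libraryId = libraryIds[j], DP = DP, RDP = DP - ADP - ODP,
            ADP = ADP)
    }
    data.table::rbindlist(out)
}

#' Simulate per-library pileups for a cohort sample
#'
#' Depth is negative-binomial per library (mean, dispersion); at each
#' position the alternative allele depth is binomial with probability
#' \code{f(1-e) + (1-f)e} where \code{f} is the sample's true allele
#' fraction (0 at reference positions) and \code{e} the per-base error
#' rate; a further error stream to non-ref non-alt bases makes
#' RDP + ADP <= DP.
#'
#' @param cohort A \code{\linkS4class{CohortTruth}}.
#' @param sample \code{"A"} for the pooled sample, or a cell line id
#'   (the normal line \code{"B"} included).
#' @param libraryIds Library identifiers (one pileup set each).
#' @param meanDepth Scalar or per-library mean depth (> 0).
#' @param dispersion Negative-binomial size parameter (default 12);
#'   \code{Inf} fixes every library's depth at its mean exactly.
#' @param errorRate Per-base error rate in [0, 0.05] (default 5e-4).
#' @param regions \code{RegionSet} of positions to emit (default: the
#'   cohort's CTR).
#' @param seed Seed.
#' @return \code{data.table(chrom, pos, libraryId, DP, RDP, ADP)}.
#' @export
simulatePileups <- function(cohort, sample, libraryIds = c("L1", "L2"),
                            meanDepth = 200, dispersion = 12,
                            errorRate = 5e-4,
                            regions = regionFile(cohort, "ctr"),
                            seed = NULL) {
    if (errorRate < 0 || errorRate > 0.05)
        stop("errorRate must be in [0, 0.05]")
    .assertPositive(meanDepth, "meanDepth")
    posTab <- regionPositions(regions)
    afTab <- .sampleAfTable(cohort, sample)
    af <- numeric(nrow(posTab))
    idx <- match(paste(posTab$chrom, posTab$pos),
                 paste(afTab$chrom, afTab$pos))
    af[!is.na(idx)] <- afTab$vaf[idx[!is.na(idx)]]
    withSeed(seed, .samplePileup(posTab, af, libraryIds, meanDepth,
                                 dispersion, errorRate))
}

## Pooled-sample locus representation relative to diploid:
## sum_i g_i * cn_i over the pool materials (1 at neutral loci).
.poolCnRel <- function(cohort, chrom, pos) {
    mats <- effectiveMaterials(cohortLines(cohort), poolRecipe(cohort))
    den <- numeric(length(pos))
    for (m in mats) {
        g <- m$mass / m$profile@basePloidy
        den <- den + g * cnAtPositions(m$profile, chrom, pos)
    }
    den
}

#' Simulate pileups for a dilution of Sample A into the normal line
#'
#' Allele fractions used for sampling are exactly
#' \code{\link{expectedDilutionVaf}} of the cohort truth (with the
#' pooled locus representation as \code{cnARel} and the normal line's own
#' allele fraction as \code{vafB}).
#'
#' @inheritParams simulatePileups
#' @param dilution A \code{\link{dilutionSpec}} (mass parts A : B).
#' @param diluentId Diluent line id (default \code{"B"}).
#' @export
simulateDilutionPileups <- function(cohort, dilution,
                                    libraryIds = c("L1", "L2", "L3"),
                                    meanDepth = 250, dispersion = 12,
                                    errorRate = 5e-4,
                                    regions = regionFile(cohort, "ctr"),
                                    diluentId = "B", seed = NULL) {
    stopifnot(inherits(dilution, "dilutionSpec"))
    posTab <- regionPositions(regions)
    aTab <- truePoolVaf(cohort)
    bTab <- trueLineVaf(cohort, diluentId)
    keys <- unique(c(aTab$key, bTab$key))
    kd <- parseVariantKey(keys)
    vafA <- numeric(length(keys)); vafB <- numeric(length(keys))
    ia <- match(keys, aTab$key); ib <- match(keys, bTab$key)
    vafA[!is.na(ia)] <- aTab$vaf[ia[!is.na(ia)]]
    vafB[!is.na(ib)] <- bTab$vaf[ib[!is.na(ib)]]
    cnRel <- .poolCnRel(cohort, kd$chrom, kd$pos)
    fDil <- expectedDilutionVaf(vafA, cnRel, vafB, dilution)
    af <- numeric(nrow(posTab))
    idx <- match(paste(posTab$chrom, posTab$pos), paste(kd$chrom, kd$pos))
    af[!is.na(idx)] <- fDil[idx[!is.na(idx)]]
    withSeed(seed, .samplePileup(posTab, af, libraryIds, meanDepth,
                                 dispersion, errorRate))
}

#' Step sensitivity curve for a pipeline profile
#'
#' @param vafBreaks Increasing VAF thresholds (left edges).
#' @param probs Detection probabilities for each interval; must be
#'   non-decreasing (detection never worsens as VAF rises).
#' @return A function VAF -> detection probability.
#' @export
sensitivityStep <- function(vafBreaks, probs) {
    stopifnot(length(vafBreaks) == length(probs), !is.unsorted(vafBreaks),
              !is.unsorted(probs))
    .assertFraction(probs, "probs")
    function(v) probs[pmax(1L, findInterval(v, vafBreaks))] *
        as.numeric(v >= vafBreaks[1L])
}

#' A pipeline x kit x library replicate (PLC) behaviour profile
#'
#' @param plcId,kitId Identifiers.
#' @param sensitivity Function VAF -> detection probability (monotone
#'   non-decreasing), e.g. from \code{\link{sensitivityStep}}.
#' @param fpRate Expected false calls per Mb of covered region.
#' @param vafNoiseSd Standard deviation of reported-VAF error.
#' @return A list with class \code{"pipelineProfile"}.
#' @export
pipelineProfile <- function(plcId, kitId, sensitivity, fpRate = 2,
                            vafNoiseSd = 0.01) {
    stopifnot(is.function(sensitivity), fpRate >= 0, vafNoiseSd >= 0)
    structure(list(plcId = plcId, kitId = kitId, sensitivity = sensitivity,
                   fpRate = fpRate, vafNoiseSd = vafNoiseSd),
              class = "pipelineProfile")
}

#' Default PLC profiles for a cohort
#'
#' One profile per PLC in the cohort's kit rosters.  WES pipelines use a
#' deep-coverage individual-line sensitivity curve (near-perfect at VAF
#' >= 10\%, 95\% in 5-10\%, degrading below); WGS callers are less
#' sensitive, reflecting their lower depth.  These defaults are
#' calibrated only to keep consensus voting non-degenerate and to
#' reproduce the qualitative cross-contamination detectability of the
#' emulated study.
#'
#' @param cohort A \code{CohortTruth}.
#' @param fpRate,vafNoiseSd Passed to every profile.
#' @return List of \code{\link{pipelineProfile}}s.
#' @export
defaultPipelineProfiles <- function(cohort, fpRate = 2, vafNoiseSd = 0.01) {
    wesSens <- sensitivityStep(c(0.005, 0.02, 0.05, 0.10),
                               c(0.10, 0.60, 0.95, 0.995))
    wgsSens <- sensitivityStep(c(0.02, 0.05, 0.10, 0.20),
                               c(0.10, 0.60, 0.90, 0.97))
    profs <- list()
    for (kit in names(cohort@kitRosters)) {
        sens <- if (kit == "WGS1") wgsSens else wesSens
        for (plc in cohort@kitRosters[[kit]])
            profs[[plc]] <- pipelineProfile(plc, kit, sens, fpRate,
                                            vafNoiseSd)
    }
    profs
}

#' Simulate noisy per-pipeline call sets on the individual cell lines
#'
#' Every true variant of a line (restricted to the profile's kit design
#' region; the WGS kit covers the whole genome) is detected with
#' probability \code{sensitivity(lineVAF)}; reported VAF is the true line
#' VAF plus truncated Gaussian noise; false positives are placed
#' uniformly in the covered region at \code{fpRate} per Mb.
#'
#' @param cohort A \code{CohortTruth}.
#' @param profiles List of \code{\link{pipelineProfile}}s.
#' @param lineIds Lines to call (default: the pooled lines).
#' @param seed Seed.
#' @return \code{data.table(plcId, kitId, lineId, chrom, pos, ref, alt,
#'   key, vaf)}.
#' @export
simulateCallsets <- function(cohort, profiles = defaultPipelineProfiles(cohort),
                             lineIds = names(poolRecipe(cohort)),
                             seed = NULL) {
    kits <- names(cohort@kitRosters)
    for (p in profiles)
        if (!p$kitId %in% kits)
            stop("profile '", p$plcId, "' names unknown kit '", p$kitId, "'")
    kitRegion <- function(kit)
        if (kit == "WGS1") regionFile(cohort, "genome")
        else regionFile(cohort, kit)
    usedKits <- unique(vapply(profiles, `[[`, character(1), "kitId"))
    withSeed(seed, {
        lineTruth <- lapply(stats::setNames(lineIds, lineIds), function(id)
            trueLineVaf(cohort, id))
        kitPos <- lapply(stats::setNames(usedKits, usedKits), function(k)
            regionPositions(kitRegion(k)))
        ## per (kit, line) truth restricted to the kit design, computed once
        kitLineTruth <- lapply(stats::setNames(usedKits, usedKits), function(k) {
            reg <- kitRegion(k)
            lapply(lineTruth, function(tv)
                tv[inRegions(reg, tv$chrom, tv$pos)])
        })
        out <- list()
        for (p in profiles) {
            reg <- kitRegion(p$kitId)
            mb <- totalLength(reg) / 1e6
            for (id in lineIds) {
                tv <- kitLineTruth[[p$kitId]][[id]]
                det <- stats::runif(nrow(tv)) < p$sensitivity(tv$vaf)
                hit <- tv[det]
                if (nrow(hit)) {
                    v <- hit$vaf + stats::rnorm(nrow(hit), 0, p$vafNoiseSd)
                    hit$vaf <- pmin(1, pmax(0, v))
                }
                nFp <- stats::rpois(1L, p$fpRate * mb)
                if (nFp > 0) {
                    ppos <- kitPos[[p$kitId]]
                    fpRows <- ppos[sample.int(nrow(ppos), min(nFp, nrow(ppos)))]
                    ref <- .randBase(nrow(fpRows))
                    fp <- data.table::data.table(
                        chrom = fpRows$chrom, pos = fpRows$pos, ref = ref,
                        alt = .randAlt(ref))
                    fp$key <- paste(fp$chrom, fp$pos, fp$ref, fp$alt,
                                    sep = ":")
                    fp$vaf <- stats::runif(nrow(fp), 0.02, 0.30)
                    hit <- rbind(hit[, c("chrom", "pos", "ref", "alt",
                                         "key", "vaf"), with = FALSE], fp)
                } else {
                    hit <- hit[, c("chrom", "pos", "ref", "alt", "key",
                                   "vaf"), with = FALSE]
                }
                if (nrow(hit)) {
                    hit$plcId <- p$plcId; hit$kitId <- p$kitId
                    hit$lineId <- id
                    out[[length(out) + 1L]] <- hit
                }
            }
        }
        if (!length(out)) {
            empty <- .emptyCalls()
            empty$plcId <- character(); empty$kitId <- character()
            empty$lineId <- character()
            data.table::setcolorder(empty, c("plcId", "kitId", "lineId",
                                             "chrom", "pos", "ref", "alt",
                                             "key", "vaf"))
            empty
        } else {
            data.table::rbindlist(out)[, c("plcId", "kitId", "lineId",
                                           "chrom", "pos", "ref", "alt",
                                           "key", "vaf"), with = FALSE]
        }
    })
}

#' Simulate one ddPCR well by Poisson partitioning
#'
#' Reference and alternative molecules are independently
#' Poisson-partitioned across droplets; the four occupancy classes are
#' multinomial with cell probabilities given by the product of the two
#' zero-class probabilities.  A small per-droplet misclassification rate
#' moves alt-negative droplets into the alt-positive classes, emulating
#' the sub-0.1\%-VAF background observed in negative samples.
#'
#' @param trueVaf True variant allele fraction in [0, 1].
#' @param genomeCopies Total template molecules loaded into the well.
#' @param nDroplets Droplet count (>= 1000).
#' @param falsePositiveRate Per-droplet alt-channel misclassification
#'   rate (default 5e-5).
#' @param seed Seed.
#' @param assayId,sampleId,inputMassNg Well annotations.
#' @return A \code{\linkS4class{DdpcrWell}}.
#' @export
simulateDdpcrWell <- function(trueVaf, genomeCopies, nDroplets = 20000L,
                              falsePositiveRate = 5e-5, seed = NULL,
                              assayId = "assay", sampleId = "S",
                              inputMassNg = NA_real_) {
    .assertFraction(trueVaf, "trueVaf")
    .assertPositive(genomeCopies, "genomeCopies")
    if (nDroplets < 1000L) stop("nDroplets must be >= 1000")
    lambdaTotal <- genomeCopies / nDroplets
    if (lambdaTotal > 10)
        stop("mean occupancy ", signif(lambdaTotal, 3),
             " exceeds 10; the well would be saturated")
    lr <- lambdaTotal * (1 - trueVaf)
    la <- lambdaTotal * trueVaf
    qr <- exp(-lr); qa <- exp(-la)
    withSeed(seed, {
        cts <- stats::rmultinom(1L, nDroplets,
                                c(qr * qa, (1 - qr) * qa,
                                  qr * (1 - qa), (1 - qr) * (1 - qa)))[, 1L]
        if (falsePositiveRate > 0) {
            flip1 <- stats::rbinom(1L, cts[1L], falsePositiveRate)
            flip2 <- stats::rbinom(1L, cts[2L], falsePositiveRate)
            cts <- cts + c(-flip1, -flip2, flip1, flip2)
        }
        new("DdpcrWell", assayId = assayId, sampleId = sampleId,
            nTotal = as.numeric(nDroplets), nDoubleNeg = as.numeric(cts[1L]),
            nRefOnly = as.numeric(cts[2L]), nAltOnly = as.numeric(cts[3L]),
            nDoublePos = as.numeric(cts[4L]), inputMassNg = inputMassNg)
    })
}

#' Read / write pileup tables as TSV
#'
#' Six tab-separated columns (\code{chrom, pos, libraryId, DP, RDP,
#' ADP}), with header.
#'
#' @param pileups A pileup \code{data.frame}.
#' @param path File path.
#' @export
writePileupTsv <- function(pileups, path) {
    data.table::fwrite(data.table::as.data.table(pileups), path, sep = "\t")
    invisible(path)
}

#' @rdname writePileupTsv
#' @export
readPileupTsv <- function(path) {
    data.table::fread(path, sep = "\t",
                      colClasses = list(character = c("chrom", "libraryId"),
                                        integer = c("pos", "DP", "RDP",
                                                    "ADP")))
}
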