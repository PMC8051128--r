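## End-to-end convenience: from a synthetic cohort through Class 1 /
## Class 2 consensus to a TruthSet, plus pooled-sample confirmation.

#' Per-kit, per-line WES consensus call sets
#'
#' For each kit and line: variants called by at least
#' \code{ceiling(voteFraction * rosterSize)} of that kit's PLCs (no VAF
#' floor; used as the WES support evidence for Class 2).
#'
#' @param calls \code{data.table} from \code{\link{simulateCallsets}}
#'   (WES kits only are used).
#' @param kitRosters Named list: kit -> PLC ids.
#' @param voteFraction Fraction of the roster required (default 0.5).
#' @return \code{data.table(kitId, lineId, key)}.
#' @export
wesKitConsensus <- function(calls, kitRosters, voteFraction = 0.5) {
    calls <- data.table::as.data.table(calls)
    out <- list()
    for (kit in setdiff(names(kitRosters), "WGS1")) {
        sub <- calls[calls$kitId == kit]
        if (!nrow(sub)) next
        need <- ceiling(voteFraction * length(kitRosters[[kit]]))
        votes <- sub[, list(n = data.table::uniqueN(plcId)),
                     by = c("lineId", "key")]
        win <- votes[votes$n >= need]
        if (nrow(win)) {
            win$kitId <- kit
            out[[kit]] <- win[, c("kitId", "lineId", "key"), with = FALSE]
        }
    }
    if (!length(out))
        return({out <- data.table::data.table(kitId = character(),
                                              lineId = character())
                out$key <- character(); out})
    data.table::rbindlist(out)
}

#' Run the full truth-set construction on simulated call sets
#'
#' Simulates per-PLC call sets, applies the per-kit Class 1 majority
#' vote and cross-kit intersection within the CTR, derives Class 2 from
#' WGS + WES-consensus support in the COSMIC high-confidence coding
#' domain outside the CTR, flags multi-allelic loci, and assembles the
#' TruthSet.
#'
#' @param cohort A \code{\linkS4class{CohortTruth}}.
#' @param profiles PLC profiles (default
#'   \code{\link{defaultPipelineProfiles}}).
#' @param cfg A \code{\link{consensusConfig}}.
#' @param seed Seed for call-set simulation.
#' @return List: \code{truthSet}, \code{calls}, \code{perKitVotes},
#'   \code{wesConsensus}, \code{wgsCalls}.
#' @export
runTruthsetPipeline <- function(cohort,
                                profiles = defaultPipelineProfiles(cohort),
                                cfg = consensusConfig(), seed = 1L) {
    calls <- simulateCallsets(cohort, profiles, seed = seed)
    ctr <- regionFile(cohort, "ctr")
    perKitVotes <- lapply(
        stats::setNames(cfg$replicatedKits, cfg$replicatedKits),
        function(kit) voteClass1Kit(calls[calls$kitId == kit],
                                    cohort@kitRosters[[kit]], cfg))
    class1 <- buildClass1(perKitVotes, ctr, cfg)
    wes <- wesKitConsensus(calls, cohort@kitRosters, cfg$voteFraction)
    wgsCalls <- calls[calls$kitId == "WGS1"]
    data.table::setnames(wgsCalls, "plcId", "caller")
    class2 <- buildClass2(wgsCalls, wes,
                          regionFile(cohort, "cosmicHcCoding"), ctr)
    perLine <- split(wes$key, wes$lineId)
    multi <- flagMultiallelic(perLine)
    truth <- assembleTruthSet(class1, class2, multi)
    list(truthSet = truth, calls = calls, perKitVotes = perKitVotes,
         wesConsensus = wes, wgsCalls = wgsCalls)
}

#' Pooled-sample consensus with merged pileup counts
#'
#' Emulates deep pooled-sample confirmation: several somatic callers
#' (one indel-only) each detect pooled variants with a
#' deep-coverage sensitivity curve; calls supported by >= \code{m}
#' callers are kept; the consensus VAF is recomputed from merged pooled
#' pileup counts at the variant positions (three kits, three libraries
#' each), not averaged from the callers.
#'
#' @param cohort A \code{CohortTruth}.
#' @param nCallers Number of callers (default 6; the last is
#'   indel-only).
#' @param m Support threshold (default 3).
#' @param kits Pooled-sample kits (default \code{c("WES1","WES2","WES3")}).
#' @param libsPerKit,meanDepth,dispersion,errorRate Pooled library model
#'   (defaults 3 libraries/kit at mean depth 250).
#' @param sens Caller sensitivity on the merged pooled sample (default:
#'   near-perfect at pooled VAF >= 0.5\%).
#' @param seed Seed.
#' @return \code{data.table(key, support, dp, adp, vaf)} of consensus
#'   calls with merged counts summed over all pooled libraries.
#' @export
pooledConsensus <- function(cohort, nCallers = 6L, m = 3L,
                            kits = c("WES1", "WES2", "WES3"),
                            libsPerKit = 3L, meanDepth = 250,
                            dispersion = 12, errorRate = 5e-4,
                            sens = sensitivityStep(
                                c(0.001, 0.002, 0.005),
                                c(0.30, 0.90, 0.998)),
                            seed = 1L) {
    truth <- truePoolVaf(cohort)
    seeds <- fanOutSeeds(seed, 2L)
    perCaller <- withSeed(seeds[1L], {
        lapply(seq_len(nCallers), function(i) {
            cand <- if (i == nCallers) truth[isIndelKey(truth$key)] else truth
            det <- stats::runif(nrow(cand)) < sens(cand$vaf)
            cand$key[det]
        })
    })
    names(perCaller) <- paste0("caller", seq_len(nCallers))
    cons <- mOfNConsensus(perCaller, m)
    if (!nrow(cons)) return(cons)
    ## merged pooled pileup counts at the consensus positions
    kd <- parseVariantKey(cons$key)
    posRegion <- RegionSet(kd$chrom, kd$pos - 1L, kd$pos, "consensusLoci")
    libIds <- unlist(lapply(kits, function(k)
        paste0(k, ".A.L", seq_len(libsPerKit))))
    pile <- simulatePileups(cohort, "A", libraryIds = libIds,
                            meanDepth = meanDepth, dispersion = dispersion,
                            errorRate = errorRate, regions = posRegion,
                            seed = seeds[2L])
    agg <- pile[, list(dp = sum(DP), adp = sum(ADP)), by = c("chrom", "pos")]
    idx <- match(paste(kd$chrom, kd$pos), paste(agg$chrom, agg$pos))
    cons$dp <- agg$dp[idx]
    cons$adp <- agg$adp[idx]
    cons$vaf <- ifelse(cons$dp > 0, cons$adp / cons$dp, NA_real_)
    cons
}

#' Write a TruthSet to disk
#'
#' Emits a VCF 4.2 of the positives (INFO carries the class) and a TSV of
#' multi-allelic exclusions.
#'
#' @param truth A \code{\linkS4class{TruthSet}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeTruthSet <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    keys <- c(class1Keys(truth), class2Keys(truth))
    kd <- parseVariantKey(keys)
    kd$vaf <- NA_real_
    cls <- rep(c(1L, 2L), c(length(class1Keys(truth)),
                            length(class2Keys(truth))))
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=CLASS,Number=1,Type=Integer,Description=\"Positive class\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    ord <- order(kd$chrom, kd$pos)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCLASS=%d",
                    kd$chrom[ord], kd$pos[ord], kd$ref[ord], kd$alt[ord],
                    cls[ord])
    writeLines(c(hdr, body), file.path(dir, "positives.vcf"))
    data.table::fwrite(multiallelicLoci(truth),
                       file.path(dir, "multiallelic_excluded.tsv"),
                       sep = "\t")
    invisible(dir)
}

#' Write a NegativeLocusTable to disk
#'
#' BED (0-based) of retained positions plus a JSON stage-count report.
#'
#' @param negatives A \code{\linkS4class{NegativeLocusTable}}.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
writeNegatives <- function(negatives, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pos <- negativePositions(negatives)
    bed <- data.table::data.table(chrom = pos$chrom, start = pos$pos - 1L,
                                  end = pos$pos)
    data.table::fwrite(bed, file.path(dir, "negatives.bed"), sep = "\t",
                       col.names = FALSE)
    jsonlite::write_json(
        list(build = "synthetic single build",
             stageCounts = as.list(stageCounts(negatives)),
             config = negatives@config),
        file.path(dir, "negatives_report.json"), auto_unbox = TRUE)
    invisible(dir)
}
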