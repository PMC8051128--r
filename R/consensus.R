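## Class 1 / Class 2 consensus voting, m-of-n single-sample consensus,
## multi-allelic exclusion, truth-set assembly and pooled confirmation.

#' Consensus voting configuration
#'
#' @param voteFraction Fraction of a kit's pipeline-library-combination
#'   (PLC) roster that must call a variant (default 0.5, "at least half");
#'   the integer threshold is \code{ceiling(voteFraction * rosterSize)}, so
#'   4 of 7 passes and 3 of 7 fails.
#' @param lineVafMin Minimum reported VAF for a call to count in Class 1
#'   voting (default 0.10).
#' @param replicatedKits Kit ids whose per-kit vote winners are intersected
#'   to form Class 1 (default the three replicated WES kits).
#' @param mOfNSupport Minimum caller support for the pooled-sample
#'   m-of-n consensus (default 3).
#' @return A list with class \code{"consensusConfig"}.
#' @export
consensusConfig <- function(voteFraction = 0.5, lineVafMin = 0.10,
                            replicatedKits = c("WES1", "WES2", "WES3"),
                            mOfNSupport = 3L) {
    if (voteFraction <= 0 || voteFraction > 1)
        stop("voteFraction must be in (0, 1]")
    .assertFraction(lineVafMin, "lineVafMin")
    structure(list(voteFraction = voteFraction, lineVafMin = lineVafMin,
                   replicatedKits = replicatedKits,
                   mOfNSupport = as.integer(mOfNSupport)),
              class = "consensusConfig")
}

#' Per-kit Class 1 majority vote
#'
#' For one kit: a variant wins on a cell line if at least
#' \code{ceiling(voteFraction * |roster|)} of the roster's PLCs call it on
#' that line with VAF at or above \code{lineVafMin}.  Per-line winners are
#' pooled (union) across lines into the kit's non-redundant variant list.
#'
#' @param calls \code{data.frame(plcId, lineId, key, vaf)} of this kit's
#'   calls.
#' @param roster Character vector of PLC ids that produced call sets for
#'   this kit (the vote denominator; absent pipelines shrink the roster
#'   rather than count as no-votes).
#' @param cfg A \code{\link{consensusConfig}}.
#' @return Character vector of winning variant keys (deduplicated).
#' @export
voteClass1Kit <- function(calls, roster, cfg = consensusConfig()) {
    if (!length(roster)) stop("roster must be non-empty")
    calls <- data.table::as.data.table(calls)
    if (nrow(calls) && !all(calls$plcId %in% roster))
        stop("call set references PLCs not on the roster: ",
             paste(setdiff(unique(calls$plcId), roster), collapse = ", "))
    if (!nrow(calls)) return(character())
    need <- as.integer(ceiling(cfg$voteFraction * length(roster)))
    ok <- calls[calls$vaf >= cfg$lineVafMin]
    if (!nrow(ok)) return(character())
    votes <- ok[, list(n = data.table::uniqueN(plcId)), by = c("lineId", "key")]
    unique(votes$key[votes$n >= need])
}

#' Cross-kit Class 1 intersection within the CTR
#'
#' @param perKitVotes Named list: kit id -> character vector of per-kit
#'   vote winners (from \code{\link{voteClass1Kit}}).
#' @param ctr The consensus target region \code{RegionSet}.
#' @param cfg A \code{\link{consensusConfig}}; every kit in
#'   \code{cfg$replicatedKits} must be present.
#' @return Character vector of Class 1 keys: the intersection over
#'   replicated kits, restricted to CTR membership.
#' @export
buildClass1 <- function(perKitVotes, ctr, cfg = consensusConfig()) {
    missing <- setdiff(cfg$replicatedKits, names(perKitVotes))
    if (length(missing))
        stop("missing per-kit votes for: ", paste(missing, collapse = ", "))
    keys <- Reduce(intersect, perKitVotes[cfg$replicatedKits])
    if (!length(keys)) return(character())
    kd <- parseVariantKey(keys)
    keys[inRegions(ctr, kd$chrom, kd$pos)]
}

#' m-of-n single-sample consensus
#'
#' A variant is kept iff at least \code{m} distinct callers support it.
#' Callers with partial domains (e.g. indel-only callers) simply
#' contribute no votes outside their domain.  Reported per-caller VAFs are
#' not averaged: the consensus VAF is recomputed downstream from pileup
#' counts (\code{\link{estimateVaf}}).
#'
#' @param perCallerCalls Named list: caller -> \code{data.frame(key, vaf)}
#'   (or a character vector of keys).
#' @param m Minimum support (default 3).
#' @return \code{data.table(key, support)} of kept variants.
#' @export
mOfNConsensus <- function(perCallerCalls, m = 3L) {
    if (m < 1L) stop("'m' must be >= 1")
    keyList <- lapply(perCallerCalls, function(x)
        unique(if (is.data.frame(x)) x$key else x))
    tal <- table(unlist(keyList, use.names = FALSE))
    keep <- names(tal)[tal >= m]
    out <- data.table::data.table(support = as.integer(tal[keep]))
    out$key <- keep
    data.table::setcolorder(out, c("key", "support"))
    out[order(key)]
}

#' Class 2 variants outside the CTR
#'
#' Candidate domain: COSMIC-gene high-confidence coding regions minus the
#' CTR.  A variant qualifies iff, on a single cell line, it was called by
#' at least two distinct WGS callers and the WES consensus of at least two
#' distinct kits.
#'
#' @param wgsCalls \code{data.frame(caller, lineId, key)} of WGS calls.
#' @param wesConsensus \code{data.frame(kitId, lineId, key)} of per-kit,
#'   per-line WES consensus calls.
#' @param cosmicHcCoding \code{RegionSet} of COSMIC high-confidence coding
#'   regions.
#' @param ctr The consensus target region.
#' @param minWgsCallers,minWesKits Support floors (default 2 each).
#' @return Character vector of Class 2 keys.
#' @export
buildClass2 <- function(wgsCalls, wesConsensus, cosmicHcCoding, ctr,
                        minWgsCallers = 2L, minWesKits = 2L) {
    wgs <- data.table::as.data.table(wgsCalls)
    wes <- data.table::as.data.table(wesConsensus)
    if (!nrow(wgs) || !nrow(wes)) return(character())
    wgsSup <- wgs[, list(nCallers = data.table::uniqueN(caller)),
                  by = c("lineId", "key")]
    wesSup <- wes[, list(nKits = data.table::uniqueN(kitId)),
                  by = c("lineId", "key")]
    sup <- merge(wgsSup, wesSup, by = c("lineId", "key"))
    sup <- sup[sup$nCallers >= minWgsCallers & sup$nKits >= minWesKits]
    keys <- unique(sup$key)
    if (!length(keys)) return(character())
    kd <- parseVariantKey(keys)
    domain <- subtractPadded(cosmicHcCoding, ctr, pad = 0L)
    keys[inRegions(domain, kd$chrom, kd$pos)]
}

#' Flag multi-allelic exclusion loci
#'
#' Loci at which distinct alternative alleles occur across cell lines
#' appear multi-allelic in the pool; they are excluded from the positive
#' lists and recorded separately.
#'
#' @param perLineVariants Named list: line id -> character vector of
#'   variant keys (or data.frame with \code{key}).
#' @return \code{data.table(chrom, pos, ref, alts)} of flagged loci
#'   (\code{alts} comma-separated).
#' @export
flagMultiallelic <- function(perLineVariants) {
    keys <- unique(unlist(lapply(perLineVariants, function(x)
        if (is.data.frame(x)) x$key else x), use.names = FALSE))
    if (!length(keys))
        return(data.table::data.table(chrom = character(), pos = integer(),
                                      ref = character(), alts = character()))
    kd <- parseVariantKey(keys)
    loci <- kd[, list(nAlt = data.table::uniqueN(alt),
                      alts = paste(sort(unique(alt)), collapse = ",")),
               by = c("chrom", "pos", "ref")]
    loci[loci$nAlt >= 2L, c("chrom", "pos", "ref", "alts"), with = FALSE]
}

#' Assemble a TruthSet with multi-allelic exclusion applied
#'
#' Drops every key at a flagged multi-allelic locus from both classes and
#' stores the exclusions on the object.
#'
#' @param class1,class2 Character vectors of keys.
#' @param multiallelic Output of \code{\link{flagMultiallelic}}.
#' @param meta Optional per-variant metadata \code{data.frame}.
#' @return A \code{\linkS4class{TruthSet}}.
#' @export
assembleTruthSet <- function(class1, class2,
                             multiallelic = flagMultiallelic(list()),
                             meta = NULL) {
    class2 <- setdiff(class2, class1)
    if (nrow(multiallelic)) {
        bad <- .locusId(multiallelic$chrom, multiallelic$pos)
        class1 <- class1[!.keyLocus(class1) %in% bad]
        class2 <- class2[!.keyLocus(class2) %in% bad]
    }
    if (is.null(meta)) {
        meta <- data.table::data.table(
            class = rep(c(1L, 2L), c(length(class1), length(class2))))
        meta$key <- c(class1, class2)
    }
    new("TruthSet", class1 = class1, class2 = class2,
        multiallelicLoci = multiallelic, meta = meta)
}

#' Confirm truth-set positives against a pooled-sample consensus
#'
#' Checks, for every truth variant, (i) detection by the pooled-sample
#' m-of-n consensus and (ii) agreement of the pooled observed VAF with the
#' expected VAF, operationalised as the expected value falling inside the
#' exact binomial confidence interval of the pooled counts at level
#' \code{1 - alpha}.
#'
#' @param truth A \code{\linkS4class{TruthSet}}.
#' @param pooledConsensus \code{data.frame(key, dp, adp)} of consensus
#'   calls on the pooled sample with merged pileup counts, or
#'   \code{data.frame(key, vaf)} when counts are unavailable (then a
#'   fixed \code{tolerance} on |observed - expected| is used).
#' @param expectedVaf \code{data.frame(key, vaf)} of expected pooled VAFs.
#' @param alpha Confidence-interval alpha for the VAF window
#'   (default 0.001, i.e. a 99.9\% interval).
#' @param tolerance Absolute VAF tolerance used only when counts are
#'   absent (default 0.02).
#' @return List: \code{fractionDetected}, \code{fractionConfirmed}
#'   (detected and within the VAF window), \code{undetected} (keys),
#'   \code{vafOutliers} (keys detected but outside the window), \code{n}.
#' @export
confirmPositives <- function(truth, pooledConsensus, expectedVaf,
                             alpha = 0.001, tolerance = 0.02) {
    keys <- c(class1Keys(truth), class2Keys(truth))
    pc <- data.table::as.data.table(pooledConsensus)
    ev <- data.table::as.data.table(expectedVaf)
    n <- length(keys)
    if (!n) stop("empty truth set")
    detected <- keys %in% pc$key
    inWindow <- rep(FALSE, n)
    idx <- match(keys, pc$key)
    eidx <- match(keys, ev$key)
    for (i in which(detected)) {
        exp_v <- ev$vaf[eidx[i]]
        if (is.na(exp_v)) next
        row <- pc[idx[i]]
        if (all(c("dp", "adp") %in% names(pc)) && !is.na(row$dp) && row$dp > 0) {
            ci <- .clopperPearson(row$adp, row$dp, 1 - alpha)
            inWindow[i] <- exp_v >= ci[1L] && exp_v <= ci[2L]
        } else if ("vaf" %in% names(pc)) {
            inWindow[i] <- abs(row$vaf - exp_v) <= tolerance
        }
    }
    list(fractionDetected = mean(detected),
         fractionConfirmed = mean(detected & inWindow),
         undetected = keys[!detected],
         vafOutliers = keys[detected & !inWindow],
         n = n)
}
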