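## Negative-locus (homozygous-reference) calling from per-library pileups:
## the exact filter cascade over individual-line libraries, the ten-line
## average reference fraction, the pooled-sample removal rule, and
## indel-adjacent exclusion.

#' Negative-locus filter configuration
#'
#' Defaults follow the published cascade exactly: per-library depth floor
#' 50; per-line merged depth floor 125 with recalculated reference
#' fraction (RF) >= 99\%; ten-line average RF >= 99.5\%; pooled-sample
#' removal of positions with total DP >= 500, ADP > 2 and AF >= 0.002
#' (conjunction, applied per kit); positions adjacent to indel calls
#' removed.
#'
#' @param libMinDp Per-library minimum depth (default 50).
#' @param lineMinDp Per-line summed minimum depth (default 125).
#' @param lineMinRf Per-line summed RF floor (default 0.99).
#' @param avgMinRf Cross-line average RF floor (default 0.995).
#' @param poolDp,poolAdp,poolAf Pooled removal thresholds (default 500,
#'   2, 0.002): a position is removed iff DP >= poolDp AND ADP > poolAdp
#'   AND AF >= poolAf in some kit's summed counts.
#' @return A list with class \code{"negativeFilterConfig"}.
#' @export
negativeFilterConfig <- function(libMinDp = 50L, lineMinDp = 125L,
                                 lineMinRf = 0.99, avgMinRf = 0.995,
                                 poolDp = 500L, poolAdp = 2L,
                                 poolAf = 0.002) {
    vals <- c(libMinDp, lineMinDp, lineMinRf, avgMinRf, poolDp, poolAdp,
              poolAf)
    if (any(vals <= 0)) stop("all thresholds must be positive")
    structure(list(libMinDp = libMinDp, lineMinDp = lineMinDp,
                   lineMinRf = lineMinRf, avgMinRf = avgMinRf,
                   poolDp = poolDp, poolAdp = poolAdp, poolAf = poolAf),
              class = "negativeFilterConfig")
}

#' Per-line negative mask from replicate library pileups
#'
#' A position is retained iff every library of the line covers it with
#' DP >= \code{libMinDp}, the library-summed depth is >=
#' \code{lineMinDp}, and the recalculated reference fraction
#' (summed RDP / summed DP) is >= \code{lineMinRf}.
#'
#' @param pileups \code{data.frame(chrom, pos, libraryId, DP, RDP, ADP)}
#'   for one line's libraries.
#' @param cfg A \code{\link{negativeFilterConfig}}.
#' @return \code{data.table(chrom, pos, DP, RDP, rf)} of retained
#'   positions with the line RF.
#' @export
lineNegativeMask <- function(pileups, cfg = negativeFilterConfig()) {
    dt <- data.table::as.data.table(pileups)
    if (anyDuplicated(dt, by = c("chrom", "pos", "libraryId")))
        stop("duplicate (position, library) pileup records")
    nLibs <- data.table::uniqueN(dt$libraryId)
    agg <- dt[, list(n = .N, minDP = min(DP), DP = sum(DP), RDP = sum(RDP)),
              by = c("chrom", "pos")]
    keep <- agg[agg$n == nLibs & agg$minDP >= cfg$libMinDp &
                agg$DP >= cfg$lineMinDp]
    keep <- keep[keep$RDP / keep$DP >= cfg$lineMinRf]
    keep$rf <- keep$RDP / keep$DP
    keep[, c("chrom", "pos", "DP", "RDP", "rf"), with = FALSE]
}

#' Cross-line average reference-fraction filter
#'
#' The unweighted mean RF across lines must reach \code{avgMinRf}
#' (boundary inclusive).  Positions must already have survived the
#' per-line mask in every line.
#'
#' @param rf Numeric vector of per-line RFs at one position, or a matrix
#'   (positions x lines).
#' @param cfg A \code{\link{negativeFilterConfig}}.
#' @return Logical (scalar or per-row vector).
#' @export
averageRfFilter <- function(rf, cfg = negativeFilterConfig()) {
    if (is.matrix(rf)) rowMeans(rf) >= cfg$avgMinRf
    else mean(rf) >= cfg$avgMinRf
}

#' Pooled-sample removal rule for one kit
#'
#' Sums DP and ADP across the kit's pooled-sample libraries; a position is
#' removed iff all three conditions hold simultaneously:
#' DP >= \code{poolDp}, ADP > \code{poolAdp} and ADP/DP >= \code{poolAf}.
#'
#' @param poolPileups \code{data.frame(chrom, pos, libraryId, DP, RDP,
#'   ADP)} for one kit's pooled-sample libraries.
#' @param cfg A \code{\link{negativeFilterConfig}}.
#' @return \code{data.table(chrom, pos, DP, ADP, af)} of removed
#'   positions.
#' @export
pooledNegativeFilter <- function(poolPileups, cfg = negativeFilterConfig()) {
    dt <- data.table::as.data.table(poolPileups)
    agg <- dt[, list(DP = sum(DP), ADP = sum(ADP)), by = c("chrom", "pos")]
    agg$af <- ifelse(agg$DP > 0, agg$ADP / agg$DP, 0)
    agg[agg$DP >= cfg$poolDp & agg$ADP > cfg$poolAdp & agg$af >= cfg$poolAf]
}

#' Remove positions adjacent to indel calls
#'
#' Convention: for each indel, the position immediately left of the
#' anchor, every reference position spanned by the indel (anchor through
#' anchor + nchar(ref) - 1), and the position immediately right of the
#' span are removed.  A deletion \code{chr1:100 ATT>A} removes 99-103; an
#' insertion \code{chr1:100 A>ATT} removes 99-101.  SNV calls trigger no
#' removals.
#'
#' @param positions \code{data.frame(chrom, pos)} of candidate negatives.
#' @param indelCalls Character vector of normalised variant keys, or a
#'   \code{data.frame(chrom, pos, ref, alt)}.
#' @return The surviving subset of \code{positions}.
#' @export
excludeIndelAdjacent <- function(positions, indelCalls) {
    pos <- data.table::as.data.table(positions)
    if (is.character(indelCalls)) indelCalls <- parseVariantKey(indelCalls)
    ind <- data.table::as.data.table(indelCalls)
    ind <- ind[nchar(ind$ref) > 1L | nchar(ind$alt) > 1L]
    if (!nrow(ind) || !nrow(pos)) return(pos)
    from <- ind$pos - 1L
    to <- ind$pos + nchar(ind$ref)   # left flank, spanned bases, right flank
    drop <- unique(paste(rep(ind$chrom, to - from + 1L),
                         unlist(Map(seq.int, from, to))))
    keepIdx <- !(paste(pos$chrom, pos$pos) %in% drop)
    pos[keepIdx]
}

#' Full negative-locus cascade
#'
#' CTR positions surviving the per-line masks in every line, passing the
#' cross-line average-RF filter, minus pooled per-kit removals, minus
#' indel-adjacent exclusions.  Counts at each stage are recorded and are
#' monotone non-increasing.  Positions with zero coverage in any line are
#' simply absent and therefore never negatives.
#'
#' @param linePileups Named list: line id -> pileup \code{data.frame} of
#'   that line's libraries (all lines required).
#' @param poolPileups Named list: kit id -> pooled-sample pileup
#'   \code{data.frame}.
#' @param indelCalls Indel keys (or data.frame) for adjacency exclusion.
#' @param ctr The consensus target region \code{RegionSet}.
#' @param cfg A \code{\link{negativeFilterConfig}}.
#' @return A \code{\linkS4class{NegativeLocusTable}} whose positions carry
#'   the cross-line average RF and the maximum per-kit pooled observed
#'   alternative allele fraction.
#' @export
callNegatives <- function(linePileups, poolPileups, indelCalls, ctr,
                          cfg = negativeFilterConfig()) {
    if (!length(linePileups)) stop("no line pileups supplied")
    if (is.null(names(linePileups)) || any(!nzchar(names(linePileups))))
        stop("linePileups must be a named list (one entry per line)")
    nLines <- length(linePileups)
    ## per-line masks, joined so only positions surviving in all lines remain
    merged <- NULL
    for (id in names(linePileups)) {
        mask <- lineNegativeMask(linePileups[[id]], cfg)
        mask <- mask[, c("chrom", "pos", "rf"), with = FALSE]
        data.table::setnames(mask, "rf", paste0("rf.", id))
        merged <- if (is.null(merged)) mask else
            merge(merged, mask, by = c("chrom", "pos"))
    }
    rfCols <- paste0("rf.", names(linePileups))
    counts <- c(lineMasks = nrow(merged))
    ## CTR restriction
    merged <- merged[inRegions(ctr, merged$chrom, merged$pos)]
    counts <- c(counts, ctr = nrow(merged))
    ## average RF
    merged$avgRF <- rowMeans(as.matrix(merged[, rfCols, with = FALSE]))
    merged <- merged[merged$avgRF >= cfg$avgMinRf]
    counts <- c(counts, avgRf = nrow(merged))
    ## pooled per-kit removal (union over kits) + per-kit observed AF
    merged$maxKitAf <- 0
    for (kit in names(poolPileups)) {
        kitAgg <- data.table::as.data.table(poolPileups[[kit]])[
            , list(DP = sum(DP), ADP = sum(ADP)), by = c("chrom", "pos")]
        kitAgg$af <- ifelse(kitAgg$DP > 0, kitAgg$ADP / kitAgg$DP, 0)
        removed <- kitAgg$DP >= cfg$poolDp & kitAgg$ADP > cfg$poolAdp &
            kitAgg$af >= cfg$poolAf
        idx <- match(paste(merged$chrom, merged$pos),
                     paste(kitAgg$chrom, kitAgg$pos))
        af <- ifelse(is.na(idx), 0, kitAgg$af[idx])
        rem <- !is.na(idx) & removed[idx]
        merged$maxKitAf <- pmax(merged$maxKitAf, af)
        merged <- merged[!rem]
    }
    counts <- c(counts, pooled = nrow(merged))
    ## indel-adjacent exclusion
    keep <- excludeIndelAdjacent(
        merged[, c("chrom", "pos"), with = FALSE], indelCalls)
    merged <- merged[paste(merged$chrom, merged$pos) %in%
                     paste(keep$chrom, keep$pos)]
    counts <- c(counts, indelAdjacent = nrow(merged))
    new("NegativeLocusTable",
        positions = merged[, c("chrom", "pos", "avgRF", "maxKitAf"),
                           with = FALSE],
        stageCounts = counts,
        config = unclass(cfg))
}
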