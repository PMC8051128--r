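## Pool and dilution VAF arithmetic, pileup-based estimation, concordance,
## and mixture-proportion regression.
##
## Pooling is by DNA mass.  A cell line contributes genome equivalents in
## proportion to massFraction / basePloidy (a tetraploid genome packs
## fewer genome copies per nanogram), so the expected pooled VAF of a
## variant is
##     sum_i g_i * altCopies_i / sum_i g_i * cn_i,   g_i = mass_i / ploidy_i
## where cn_i is the local copy number of line i at the locus.

## copy number of a profile at given positions (vectorised)
cnAtPositions <- function(profile, chrom, pos) {
    out <- rep(profile@basePloidy, length(pos))
    seg <- profile@cnaSegments
    if (length(seg) && length(pos)) {
        q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
        hits <- GenomicRanges::findOverlaps(q, seg, ignore.strand = TRUE)
        out[S4Vectors::queryHits(hits)] <-
            S4Vectors::mcols(seg)$cn[S4Vectors::subjectHits(hits)]
    }
    as.integer(out)
}

## Expand contamination events into effective "material" profiles with
## adjusted masses.  `lines` is a named list of CellLineProfile; `masses`
## a named numeric over (a subset of) those lines.  A line with
## contamination (other, r) contributes mass m/(1+r) of itself and
## m*r/(1+r) of the contaminant line's profile.
effectiveMaterials <- function(lines, masses) {
    mats <- list()
    for (id in names(masses)) {
        if (!id %in% names(lines)) stop("unknown cell line '", id, "'")
        p <- lines[[id]]
        m <- masses[[id]]
        if (is.null(p@contamination)) {
            mats[[length(mats) + 1L]] <- list(profile = p, mass = m)
        } else {
            other <- p@contamination$otherLineId
            if (!other %in% names(lines))
                stop("contamination of '", id, "' references unknown line '",
                     other, "'")
            r <- p@contamination$massRatio
            mats[[length(mats) + 1L]] <- list(profile = p, mass = m / (1 + r))
            mats[[length(mats) + 1L]] <- list(profile = lines[[other]],
                                              mass = m * r / (1 + r))
        }
    }
    mats
}

## Expected VAF table over a set of keys for given materials.
## Returns data.table(key, chrom, pos, ref, alt, vaf).
.poolVafTable <- function(lines, masses, keys = NULL) {
    if (abs(sum(masses) - 1) > 1e-9)
        stop("mass fractions must sum to 1 (tolerance 1e-9)")
    mats <- effectiveMaterials(lines, masses)
    if (is.null(keys)) {
        keys <- unique(unlist(lapply(mats, function(m)
            m$profile@genotypes$key)))
    }
    kd <- parseVariantKey(keys)
    num <- numeric(nrow(kd))
    den <- numeric(nrow(kd))
    for (m in mats) {
        g <- m$mass / m$profile@basePloidy
        if (g == 0) next
        cn <- cnAtPositions(m$profile, kd$chrom, kd$pos)
        geno <- data.table::as.data.table(m$profile@genotypes)
        altc <- numeric(nrow(kd))
        if (nrow(geno)) {
            idx <- match(kd$key, geno$key)
            hit <- !is.na(idx)
            altc[hit] <- geno$altCopies[idx[hit]]
            ## the genotype's stated total copies takes precedence at
            ## carried loci (it was assigned from the covering segment)
            cn[hit] <- geno$totalCopies[idx[hit]]
        }
        num <- num + g * altc
        den <- den + g * cn
    }
    if (any(den == 0))
        stop("no pooled line covers locus ", kd$key[which(den == 0)[1L]],
             " (all-zero copy number)")
    kd$vaf <- num / den
    kd[]
}

#' Expected pooled-sample VAF of a variant
#'
#' Mass-pool model: each line contributes genome equivalents
#' \code{massFraction / basePloidy}; the expected VAF at a locus is the
#' genome-equivalent- and copy-number-weighted alternative allele fraction.
#' A heterozygous variant private to one of ten equal-mass diploid lines
#' comes out at 5\%, a homozygous one at 10\%.
#'
#' @param lines A named list of \code{\linkS4class{CellLineProfile}} whose
#'   \code{massFraction}s sum to 1, or a \code{\linkS4class{CohortTruth}}
#'   (whose pool recipe is used).
#' @param key Character vector of variant keys (\code{"chrom:pos:ref:alt"}).
#' @return Numeric vector of expected VAFs in [0, 1].
#' @export
expectedPoolVaf <- function(lines, key) {
    if (is(lines, "CohortTruth")) {
        masses <- poolRecipe(lines)
        lines <- cohortLines(lines)
    } else {
        if (is.null(names(lines)))
            names(lines) <- vapply(lines, function(p) p@lineId, character(1))
        masses <- vapply(lines, function(p) p@massFraction, numeric(1))
    }
    tab <- .poolVafTable(lines, masses, keys = key)
    tab$vaf
}

#' Expected within-line VAF table, honouring contamination
#'
#' The effective allele fractions of a (possibly contaminated) cell line's
#' DNA: for a pure line this is \code{altCopies / totalCopies}; for a
#' contaminated line the host and contaminant materials are mass-weighted.
#'
#' @param cohort A \code{CohortTruth}.
#' @param lineId Cell line id.
#' @return \code{data.table(key, chrom, pos, ref, alt, vaf)} over the union
#'   of the involved lines' variants.
#' @export
trueLineVaf <- function(cohort, lineId) {
    lines <- cohortLines(cohort)
    if (!lineId %in% names(lines)) stop("unknown cell line '", lineId, "'")
    masses <- stats::setNames(1, lineId)
    .poolVafTable(lines, masses)
}

#' Dilution specification (mass parts of Sample A to diluent B)
#'
#' @param partsA,partsB Non-negative mass parts (sum > 0).  The mixing
#'   fraction is \code{alpha = partsA / (partsA + partsB)}.
#' @return A list with class \code{"dilutionSpec"}.
#' @examples
#' dilutionSpec(1, 24)  # Sample E
#' @export
dilutionSpec <- function(partsA, partsB) {
    if (partsA < 0 || partsB < 0 || partsA + partsB <= 0)
        stop("dilution parts must be non-negative with a positive sum")
    structure(list(partsA = partsA, partsB = partsB,
                   alpha = partsA / (partsA + partsB)),
              class = "dilutionSpec")
}

#' Expected VAF after diluting Sample A into diluent B
#'
#' @param vafA Variant VAF in Sample A, in [0, 1].
#' @param cnARel Sample A locus representation relative to diploid
#'   (genome-equivalent-weighted mean copy number / 2); 1 for neutral loci.
#' @param vafB Variant VAF in the diluent (0 for A-private variants).
#' @param dilution A \code{\link{dilutionSpec}}.
#' @return \code{(alpha * cnARel * vafA + (1 - alpha) * vafB) /
#'   (alpha * cnARel + (1 - alpha))}; reduces to \code{alpha * vafA} for
#'   neutral copy number and an absent-in-B variant.
#' @examples
#' expectedDilutionVaf(0.005, 1, 0, dilutionSpec(1, 24))  # 0.0002 (0.02%)
#' @export
expectedDilutionVaf <- function(vafA, cnARel = 1, vafB = 0, dilution) {
    stopifnot(inherits(dilution, "dilutionSpec"))
    .assertFraction(vafA, "vafA"); .assertFraction(vafB, "vafB")
    .assertPositive(cnARel, "cnARel")
    a <- dilution$alpha
    (a * cnARel * vafA + (1 - a) * vafB) / (a * cnARel + (1 - a))
}

#' Pileup-based VAF estimation over merge groups
#'
#' Counts are summed within each merge group (e.g. the replicate libraries
#' of one kit's merged pooled-sample alignment), the VAF computed from the
#' summed counts, and an exact binomial (Clopper-Pearson) confidence
#' interval attached.  The final cross-kit estimate is the unweighted mean
#' of the per-group VAFs.  Counts are assumed to already reflect upstream
#' read filtering (minimum mapping quality 1, minimum base quality 5).
#'
#' @param counts \code{data.frame(libraryId, DP, ADP)} at one variant.
#' @param mergeGroups Named list of character vectors of library ids.
#' @param conf Confidence level for the per-group interval (default 0.95).
#' @return List with \code{groups} (a \code{data.table(group, dp, adp,
#'   vaf, lo, hi)}; a zero-depth group is flagged \code{NA}, not zero) and
#'   \code{final} (mean of non-missing group VAFs).
#' @export
estimateVaf <- function(counts, mergeGroups, conf = 0.95) {
    counts <- data.table::as.data.table(counts)
    if (is.null(names(mergeGroups)))
        names(mergeGroups) <- paste0("group", seq_along(mergeGroups))
    rows <- lapply(names(mergeGroups), function(gname) {
        libs <- mergeGroups[[gname]]
        sub <- counts[counts$libraryId %in% libs]
        dp <- sum(sub$DP); adp <- sum(sub$ADP)
        if (dp == 0) {
            data.table::data.table(group = gname, dp = 0L, adp = 0L,
                                   vaf = NA_real_, lo = NA_real_, hi = NA_real_)
        } else {
            ci <- .clopperPearson(adp, dp, conf)
            data.table::data.table(group = gname, dp = dp, adp = adp,
                                   vaf = adp / dp, lo = ci[1L], hi = ci[2L])
        }
    })
    groups <- data.table::rbindlist(rows)
    list(groups = groups,
         final = if (all(is.na(groups$vaf))) NA_real_
                 else mean(groups$vaf, na.rm = TRUE))
}

#' Linear or log-scale concordance of two VAF series
#'
#' Ordinary least squares of \code{y} on \code{x} on the requested scale.
#' On the log10 scale, pairs with a non-positive member are dropped and
#' the number dropped is reported.
#'
#' @param x,y Equal-length numeric vectors (length >= 3 after dropping).
#' @param scale \code{"linear"} or \code{"log10"}.
#' @return List: \code{rSquared}, \code{slope}, \code{intercept}, \code{n},
#'   \code{nDropped}.
#' @export
concordance <- function(x, y, scale = c("linear", "log10")) {
    scale <- match.arg(scale)
    stopifnot(length(x) == length(y))
    nDropped <- 0L
    if (scale == "log10") {
        keep <- x > 0 & y > 0
        nDropped <- sum(!keep)
        x <- log10(x[keep]); y <- log10(y[keep])
    }
    if (length(x) < 3L) stop("need at least 3 usable pairs")
    if (stats::var(x) == 0) stop("zero variance in x")
    fit <- stats::lm(y ~ x)
    rss <- sum(stats::residuals(fit)^2)
    tss <- sum((y - mean(y))^2)
    list(rSquared = if (tss == 0) 1 else 1 - rss / tss,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         n = length(x), nDropped = nDropped)
}

#' Cell-line mixture proportion regression
#'
#' Least-squares fit (no intercept) of pooled-sample VAFs on the per-line
#' VAF design matrix (zero where a line lacks the variant).  On
#' copy-number-neutral private variants the coefficients estimate the pool
#' mass fractions.  VAF-based mixture prediction is intrinsically unstable
#' under heavy structural variation, so the residual standard deviation is
#' carried in the result.
#'
#' @param poolVafs \code{data.frame(key, vaf)} of pooled-sample VAFs.
#' @param lineVafs \code{data.frame(lineId, key, vaf)} of per-line VAFs.
#' @param subset \code{"private"} (default): restrict to variants observed
#'   (VAF > 0) in exactly one line; \code{"all"}: use every shared key.
#' @param nonneg Constrain coefficients to be non-negative (via
#'   \code{pracma::lsqnonneg}).
#' @return A \code{\linkS4class{MixtureFit}}.
#' @export
estimateMixture <- function(poolVafs, lineVafs, subset = c("private", "all"),
                            nonneg = FALSE) {
    subset <- match.arg(subset)
    poolVafs <- data.table::as.data.table(poolVafs)
    lineVafs <- data.table::as.data.table(lineVafs)
    lineIds <- sort(unique(lineVafs$lineId))
    wide <- data.table::dcast(lineVafs, key ~ lineId, value.var = "vaf",
                              fill = 0, fun.aggregate = mean)
    if (subset == "private") {
        carriers <- rowSums(as.matrix(wide[, -1L]) > 0)
        wide <- wide[carriers == 1L]
        perLine <- colSums(as.matrix(wide[, -1L]) > 0)
        if (any(perLine < 2L))
            stop("need >= 2 private variants per line; deficient: ",
                 paste(names(perLine)[perLine < 2L], collapse = ", "))
    }
    merged <- merge(wide, poolVafs[, c("key", "vaf")], by = "key")
    if (!nrow(merged)) stop("no shared variant keys between pool and lines")
    X <- as.matrix(merged[, lineIds, with = FALSE])
    y <- merged$vaf
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dep <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
        stop("rank-deficient design; collinear lines: ",
             paste(dep, collapse = ", "))
    }
    if (nonneg) {
        fit <- pracma::lsqnonneg(X, y)
        beta <- stats::setNames(fit$x, lineIds)
        resid <- y - X %*% beta
    } else {
        fit <- stats::lm.fit(X, y)
        beta <- stats::setNames(fit$coefficients, lineIds)
        resid <- fit$residuals
    }
    df <- max(1L, length(y) - ncol(X))
    new("MixtureFit", coefficients = beta,
        residualSd = sqrt(sum(resid^2) / df),
        designNote = sprintf("OLS%s of pool VAF on %d line-VAF columns, %d %s variants",
                             if (nonneg) " (nonneg)" else "", ncol(X),
                             nrow(merged), subset))
}

#' Detect cross-line contamination from call-set and CNA overlap
#'
#' For each ordered pair of lines (X, Y), computes the fraction of X's
#' called variants that also appear in Y's calls, and (optionally) the
#' fraction of X's CNA segment span overlapped by Y's CNA span.  Pairs
#' whose variant overlap meets the threshold are flagged: a contaminated
#' sample carries nearly all of the contaminant's variants at reduced VAF.
#'
#' @param lineCalls Named list: line id -> character vector of variant keys
#'   (or a data.frame with a \code{key} column).
#' @param lineCna Optional named list: line id -> \code{GRanges} of CNA
#'   segments.
#' @param variantThreshold Flagging threshold on variant overlap
#'   (default 0.90).
#' @return \code{data.table(lineX, lineY, variantOverlap, cnaOverlap,
#'   flagged)} over ordered pairs.
#' @export
detectContamination <- function(lineCalls, lineCna = NULL,
                                variantThreshold = 0.90) {
    ids <- names(lineCalls)
    if (length(ids) < 2L) stop("need at least two lines")
    keysOf <- function(x) if (is.data.frame(x)) unique(x$key) else unique(x)
    sets <- lapply(lineCalls, keysOf)
    out <- list()
    for (x in ids) for (y in setdiff(ids, x)) {
        vo <- if (length(sets[[x]]))
            length(intersect(sets[[x]], sets[[y]])) / length(sets[[x]]) else 0
        co <- NA_real_
        if (!is.null(lineCna) && x %in% names(lineCna) && y %in% names(lineCna)) {
            gx <- GenomicRanges::reduce(granges(lineCna[[x]]))
            gy <- GenomicRanges::reduce(granges(lineCna[[y]]))
            spanX <- sum(as.numeric(GenomicRanges::width(gx)))
            co <- if (spanX == 0) 0 else
                sum(as.numeric(GenomicRanges::width(suppressWarnings(
                    GenomicRanges::intersect(gx, gy, ignore.strand = TRUE))))) / spanX
        }
        out[[length(out) + 1L]] <- data.table::data.table(
            lineX = x, lineY = y, variantOverlap = vo, cnaOverlap = co,
            flagged = vo >= variantThreshold)
    }
    data.table::rbindlist(out)
}
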