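#' @import methods
#' @importFrom GenomicRanges GRanges granges findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @import data.table
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' RegionSet: sorted disjoint genomic intervals
#'
#' A named set of disjoint, sorted, strand-less genomic intervals, the
#' currency of consensus-target-region construction and membership tests.
#' Intervals are stored 1-based closed (as a \code{GRanges}) but the
#' constructor and the BED reader/writer speak 0-based half-open
#' coordinates, so on-disk conventions match BED.  Construction always
#' normalises to reduced (merged-adjacent) form so equality is structural.
#'
#' @slot ranges A reduced, sorted \code{GRanges} with no metadata columns.
#' @slot name Scalar character label for the set.
#' @export
setClass("RegionSet", representation(ranges = "GRanges", name = "character"))

setValidity("RegionSet", function(object) {
    r <- object@ranges
    if (length(object@name) != 1L) return("'name' must be a scalar")
    if (length(r) > 1L) {
        red <- GenomicRanges::reduce(r, min.gapwidth = 0L)
        if (length(red) != length(r))
            return("intervals must be disjoint, sorted and merged")
    }
    TRUE
})

#' CellLineProfile: one cell line's genomic state
#'
#' Genotypes, copy-number segments, ploidy and pool mass fraction for one
#' cell line, with an optional cross-line contamination record (the study
#' design this emulates contains one such event: the original B-lymphocyte
#' line was received admixed with the T-lymphoblast line).
#'
#' @slot lineId Scalar character identifier.
#' @slot massFraction Fraction of pool DNA mass in [0, 1].
#' @slot basePloidy Positive integer ploidy (2 for diploid lines, 4 for the
#'   tetraploid line).
#' @slot cnaSegments \code{GRanges} with an integer \code{cn} metadata
#'   column giving absolute copy number over each altered segment;
#'   uncovered positions are at \code{basePloidy}.
#' @slot genotypes \code{data.table} with columns \code{chrom, pos, ref,
#'   alt, key, altCopies, totalCopies, somatic}.  \code{totalCopies} equals
#'   the copy number of the covering segment (or \code{basePloidy}).
#' @slot contamination \code{NULL}, or \code{list(otherLineId=, massRatio=)}
#'   where \code{massRatio} is contaminant:host DNA mass.
#' @export
setClass("CellLineProfile", representation(
    lineId = "character", massFraction = "numeric", basePloidy = "integer",
    cnaSegments = "GRanges", genotypes = "data.frame",
    contamination = "listOrNULL"))

setValidity("CellLineProfile", function(object) {
    g <- object@genotypes
    need <- c("chrom", "pos", "ref", "alt", "key", "altCopies",
              "totalCopies", "somatic")
    if (!all(need %in% names(g)))
        return(paste("genotypes must have columns:", paste(need, collapse = ", ")))
    if (nrow(g) && any(g$altCopies > g$totalCopies))
        return("altCopies must not exceed totalCopies")
    if (nrow(g) && any(g$altCopies < 0))
        return("altCopies must be non-negative")
    if (object@massFraction < 0 || object@massFraction > 1)
        return("massFraction must be in [0, 1]")
    if (object@basePloidy < 1L) return("basePloidy must be positive")
    if (!is.null(object@contamination)) {
        if (!all(c("otherLineId", "massRatio") %in% names(object@contamination)))
            return("contamination needs otherLineId and massRatio")
        if (object@contamination$massRatio <= 0)
            return("contamination massRatio must be positive")
    }
    TRUE
})

#' CohortTruth: a generated cohort with full ground truth
#'
#' @slot lines Named list of \code{CellLineProfile} (pool members and the
#'   normal diluent line).
#' @slot poolRecipe Named numeric of mass fractions for pooled Sample A;
#'   sums to 1.
#' @slot truePoolVaf \code{data.table} with columns \code{key, chrom, pos,
#'   ref, alt, vaf} giving the expected pooled-sample VAF of every variant,
#'   computed by the pool VAF model on the same profiles.
#' @slot regionFiles Named list of \code{RegionSet} used in generation
#'   (kit designs, coding, high-confidence, low-complexity, cosmic, ctr).
#' @slot contigs Named numeric of contig lengths.
#' @slot kitRosters Named list: kit id -> character vector of PLC ids.
#' @export
setClass("CohortTruth", representation(
    lines = "list", poolRecipe = "numeric", truePoolVaf = "data.frame",
    regionFiles = "list", contigs = "numeric", kitRosters = "list"))

setValidity("CohortTruth", function(object) {
    if (abs(sum(object@poolRecipe) - 1) > 1e-9)
        return("pool mass fractions must sum to 1 (tolerance 1e-9)")
    if (!all(names(object@poolRecipe) %in% names(object@lines)))
        return("poolRecipe names must be cohort line ids")
    TRUE
})

#' TruthSet: Class 1 / Class 2 positives with exclusions
#'
#' @slot class1 Character vector of normalised variant keys inside the
#'   consensus target region, found by per-kit majority vote and cross-kit
#'   intersection.
#' @slot class2 Character vector of keys outside the CTR (COSMIC
#'   high-confidence coding domain) supported by two WGS callers and two
#'   WES kit consensuses on the same line.
#' @slot multiallelicLoci \code{data.table(chrom, pos, ref, alts)} of loci
#'   excluded because distinct alternative alleles occur across lines.
#' @slot meta \code{data.table} of per-variant provenance (class,
#'   contributing lines, per-kit votes, final VAF slot).
#' @export
setClass("TruthSet", representation(
    class1 = "character", class2 = "character",
    multiallelicLoci = "data.frame", meta = "data.frame"))

setValidity("TruthSet", function(object) {
    if (length(intersect(object@class1, object@class2)))
        return("class1 and class2 must be disjoint")
    if (nrow(object@multiallelicLoci)) {
        bad <- .keyLocus(c(object@class1, object@class2)) %in%
            .locusId(object@multiallelicLoci$chrom, object@multiallelicLoci$pos)
        if (any(bad)) return("multi-allelic loci must not appear in either class")
    }
    TRUE
})

#' NegativeLocusTable: known-negative positions with cascade provenance
#'
#' @slot positions \code{data.table(chrom, pos, avgRF, maxKitAf)} of
#'   retained positions: the ten-line unweighted mean reference-allele
#'   fraction and the maximum per-kit pooled observed alternative allele
#'   fraction at each position.
#' @slot stageCounts Named numeric of position counts after each cascade
#'   stage (monotone non-increasing).
#' @slot config The \code{negativeFilterConfig} list used.
#' @export
setClass("NegativeLocusTable", representation(
    positions = "data.frame", stageCounts = "numeric", config = "list"))

#' DdpcrWell: four-way droplet occupancy counts
#'
#' @slot assayId,sampleId Scalar character identifiers.
#' @slot nTotal Total droplet count.
#' @slot nDoubleNeg,nRefOnly,nAltOnly,nDoublePos Occupancy counts; they sum
#'   to \code{nTotal}.
#' @slot inputMassNg DNA input mass in nanograms (informational).
#' @export
setClass("DdpcrWell", representation(
    assayId = "character", sampleId = "character", nTotal = "numeric",
    nDoubleNeg = "numeric", nRefOnly = "numeric", nAltOnly = "numeric",
    nDoublePos = "numeric", inputMassNg = "numeric"))

setValidity("DdpcrWell", function(object) {
    cts <- c(object@nDoubleNeg, object@nRefOnly, object@nAltOnly,
             object@nDoublePos)
    if (any(cts < 0)) return("occupancy counts must be non-negative")
    if (sum(cts) != object@nTotal)
        return("occupancy counts must sum to nTotal")
    TRUE
})

#' MixtureFit: cell-line mixture proportion regression result
#'
#' @slot coefficients Named numeric of fitted genome-equivalent mixing
#'   coefficients (one per cell line).
#' @slot residualSd Residual standard deviation of the fit, reported
#'   prominently because VAF-based mixture prediction is intrinsically
#'   noisy under copy-number heterogeneity.
#' @slot designNote Character description of the design matrix and subset.
#' @export
setClass("MixtureFit", representation(
    coefficients = "numeric", residualSd = "numeric", designNote = "character"))

setValidity("MixtureFit", function(object) {
    if (any(!is.finite(object@coefficients))) return("coefficients must be finite")
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "RegionSet", function(object) {
    cat(sprintf("RegionSet '%s': %d intervals, total length %s bp\n",
                object@name, length(object@ranges),
                format(totalLength(object), big.mark = ",")))
})

setMethod("show", "CellLineProfile", function(object) {
    cat(sprintf("CellLineProfile %s: mass %.3f, ploidy %d, %d variants, %d CNA segments%s\n",
                object@lineId, object@massFraction, object@basePloidy,
                nrow(object@genotypes), length(object@cnaSegments),
                if (is.null(object@contamination)) "" else
                    sprintf(", contaminated by %s (%.2g:1 by mass)",
                            object@contamination$otherLineId,
                            object@contamination$massRatio)))
})

setMethod("show", "CohortTruth", function(object) {
    cat(sprintf("CohortTruth: %d lines (%d pooled), %d truth variants, %d region sets\n",
                length(object@lines), length(object@poolRecipe),
                nrow(object@truePoolVaf), length(object@regionFiles)))
})

setMethod("show", "TruthSet", function(object) {
    cat(sprintf("TruthSet: %d Class 1, %d Class 2, %d multi-allelic loci excluded\n",
                length(object@class1), length(object@class2),
                nrow(object@multiallelicLoci)))
})

setMethod("show", "NegativeLocusTable", function(object) {
    cat("NegativeLocusTable:", nrow(object@positions), "retained positions\n")
    cat("  cascade:", paste(sprintf("%s=%d", names(object@stageCounts),
                                    object@stageCounts), collapse = " -> "), "\n")
})

setMethod("show", "DdpcrWell", function(object) {
    cat(sprintf("DdpcrWell %s/%s: %d droplets (NN=%d, R=%d, A=%d, RA=%d)\n",
                object@assayId, object@sampleId, object@nTotal,
                object@nDoubleNeg, object@nRefOnly, object@nAltOnly,
                object@nDoublePos))
})

setMethod("show", "MixtureFit", function(object) {
    cat("MixtureFit (", object@designNote, ")\n", sep = "")
    print(round(object@coefficients, 4))
    cat("residual sd:", signif(object@residualSd, 4), "\n")
})

## ---- accessors ----------------------------------------------------------

#' @rdname RegionSet-class
#' @param x A \code{RegionSet}.
#' @export
regionRanges <- function(x) x@ranges

#' @rdname RegionSet-class
#' @export
regionName <- function(x) x@name

#' Total length of a RegionSet in bases
#' @param x A \code{RegionSet}.
#' @return Integer sum of interval widths.
#' @export
totalLength <- function(x) sum(as.numeric(GenomicRanges::width(x@ranges)))

#' @rdname CohortTruth-class
#' @param x A \code{CohortTruth}.
#' @export
cohortLines <- function(x) x@lines

#' @rdname CohortTruth-class
#' @export
poolRecipe <- function(x) x@poolRecipe

#' @rdname CohortTruth-class
#' @export
truePoolVaf <- function(x) data.table::copy(data.table::as.data.table(x@truePoolVaf))

#' @rdname CohortTruth-class
#' @param name Region set name (e.g. \code{"ctr"}, \code{"coding"}).
#' @export
regionFile <- function(x, name) {
    if (!name %in% names(x@regionFiles))
        stop("no region set named '", name, "'; available: ",
             paste(names(x@regionFiles), collapse = ", "))
    x@regionFiles[[name]]
}

#' @rdname CohortTruth-class
#' @param id Cell line id.
#' @export
lineProfile <- function(x, id) {
    if (!id %in% names(x@lines)) stop("unknown cell line '", id, "'")
    x@lines[[id]]
}

#' @rdname TruthSet-class
#' @param x A \code{TruthSet}.
#' @export
class1Keys <- function(x) x@class1

#' @rdname TruthSet-class
#' @export
class2Keys <- function(x) x@class2

#' @rdname TruthSet-class
#' @export
multiallelicLoci <- function(x) data.table::copy(data.table::as.data.table(x@multiallelicLoci))

#' @rdname NegativeLocusTable-class
#' @param x A \code{NegativeLocusTable}.
#' @export
negativePositions <- function(x) data.table::copy(data.table::as.data.table(x@positions))

#' @rdname NegativeLocusTable-class
#' @export
stageCounts <- function(x) x@stageCounts

#' @rdname MixtureFit-class
#' @param x A \code{MixtureFit}.
#' @export
mixtureCoefficients <- function(x) x@coefficients

#' @rdname MixtureFit-class
#' @export
residualSd <- function(x) x@residualSd

#' Construct a CellLineProfile
#'
#' @param lineId Scalar identifier.
#' @param massFraction Fraction of pool DNA mass.
#' @param basePloidy Base ploidy (2 diploid, 4 tetraploid).
#' @param genotypes A genotype table from \code{\link{genotypeTable}} (or
#'   \code{NULL} for a variant-free line).
#' @param cnaSegments \code{GRanges} with a \code{cn} metadata column, or
#'   \code{NULL}.
#' @param contamination \code{list(otherLineId=, massRatio=)} or
#'   \code{NULL}; \code{massRatio} is contaminant:host mass.
#' @return A \code{\linkS4class{CellLineProfile}}.
#' @export
cellLineProfile <- function(lineId, massFraction, basePloidy = 2L,
                            genotypes = NULL, cnaSegments = NULL,
                            contamination = NULL) {
    new("CellLineProfile", lineId = lineId, massFraction = massFraction,
        basePloidy = as.integer(basePloidy),
        cnaSegments = if (is.null(cnaSegments)) GenomicRanges::GRanges()
                      else cnaSegments,
        genotypes = if (is.null(genotypes)) .emptyGenotypes() else genotypes,
        contamination = contamination)
}

#' Build a genotype table for a cell line profile
#'
#' @param chrom,pos,ref,alt Variant identity fields (vectors).
#' @param altCopies Alternative-allele copies at each locus.
#' @param totalCopies Total copies at each locus (the local copy number).
#' @param somatic Logical flag per variant (default germline).
#' @return \code{data.table} in the layout expected by
#'   \code{\link{cellLineProfile}}.
#' @export
genotypeTable <- function(chrom, pos, ref, alt, altCopies, totalCopies,
                          somatic = FALSE) {
    out <- data.table::data.table(
        chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
        altCopies = as.integer(altCopies),
        totalCopies = as.integer(totalCopies),
        somatic = rep_len(somatic, length(chrom)))
    out$key <- paste(chrom, pos, ref, alt, sep = ":")
    data.table::setcolorder(out, c("chrom", "pos", "ref", "alt", "key",
                                   "altCopies", "totalCopies", "somatic"))
    out
}

## internal locus helpers shared by TruthSet validity and consensus code
.locusId <- function(chrom, pos) paste(chrom, pos, sep = ":")
.keyLocus <- function(keys) {
    parts <- strsplit(keys, ":", fixed = TRUE)
    vapply(parts, function(p) paste(p[1L], p[2L], sep = ":"), character(1))
}
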