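#' Construct a RegionSet from 0-based half-open intervals
#'
#' @param chrom Character vector of contig names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends (\code{start < end}).
#' @param name Scalar label for the set.
#' @return A \code{\linkS4class{RegionSet}} in normal form: sorted,
#'   disjoint, adjacent intervals merged.
#' @examples
#' rs <- RegionSet("chr1", 0, 100)
#' totalLength(rs)
#' @export
RegionSet <- function(chrom = character(), start = integer(),
                      end = integer(), name = "") {
    if (length(chrom)) {
        if (any(start >= end)) stop("intervals must satisfy start < end")
        if (any(start < 0)) stop("starts must be >= 0")
        gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
        gr <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 0L)
    } else {
        gr <- GenomicRanges::GRanges()
    }
    new("RegionSet", ranges = gr, name = name)
}

## Wrap an arbitrary GRanges as a normalised RegionSet.
asRegionSet <- function(gr, name = "") {
    gr <- GenomicRanges::reduce(GenomicRanges::sort(granges(gr)),
                                min.gapwidth = 0L)
    new("RegionSet", ranges = gr, name = name)
}

#' Intersect a list of RegionSets
#'
#' A base is in the result iff every input set contains it.  Idempotent and
#' commutative; intersecting a single set returns it unchanged.
#'
#' @param sets Non-empty list of \code{RegionSet}.
#' @param name Name for the result.
#' @return A \code{RegionSet}.
#' @export
intersectAll <- function(sets, name = "intersection") {
    if (!length(sets)) stop("need at least one RegionSet")
    grs <- lapply(sets, regionRanges)
    out <- Reduce(function(a, b)
        suppressWarnings(GenomicRanges::intersect(a, b, ignore.strand = TRUE)),
        grs)
    asRegionSet(out, name)
}

#' Subtract a padded exclusion set from a base set
#'
#' Every exclusion interval is first widened by \code{pad} bases on each
#' end (clamped at position 0; contig ends are unknown to a RegionSet so
#' the right edge is not clamped), then removed from \code{base}.
#'
#' @param base,exclusion \code{RegionSet}s.
#' @param pad Non-negative integer padding in bases.
#' @return A \code{RegionSet}, a subset of \code{base}.
#' @export
subtractPadded <- function(base, exclusion, pad = 0L) {
    if (pad < 0) stop("'pad' must be >= 0")
    ex <- regionRanges(exclusion)
    if (length(ex) && pad > 0) {
        ex <- GenomicRanges::GRanges(
            GenomeInfoDb::seqnames(ex),
            IRanges::IRanges(pmax(1L, GenomicRanges::start(ex) - as.integer(pad)),
                             GenomicRanges::end(ex) + as.integer(pad)))
    }
    out <- suppressWarnings(
        GenomicRanges::setdiff(regionRanges(base), ex, ignore.strand = TRUE))
    asRegionSet(out, regionName(base))
}

#' Build the consensus target region (CTR)
#'
#' The CTR is the intersection of all enrichment-kit design regions, the
#' coding regions, and every high-confidence region set, with the
#' pad-widened low-complexity regions excluded last.
#'
#' @param kitDesigns List of at least two kit-design \code{RegionSet}s.
#' @param coding Coding-region \code{RegionSet}.
#' @param highConfidence List of high-confidence \code{RegionSet}s (one per
#'   benchmark genome).
#' @param lowComplexity Low-complexity \code{RegionSet} to exclude.
#' @param pad Padding (bases) applied to each low-complexity interval
#'   before exclusion; default 5.
#' @return A \code{RegionSet} named \code{"ctr"}.
#' @export
buildCtr <- function(kitDesigns, coding, highConfidence, lowComplexity,
                     pad = 5L) {
    sets <- c(kitDesigns, list(coding), highConfidence)
    universe <- unique(as.character(GenomeInfoDb::seqnames(
        regionRanges(kitDesigns[[1L]]))))
    for (s in sets) {
        chs <- unique(as.character(GenomeInfoDb::seqnames(regionRanges(s))))
        if (length(chs) && length(universe) && !any(chs %in% universe))
            stop("region set '", regionName(s),
                 "' shares no contigs with the kit designs")
    }
    core <- intersectAll(sets, name = "ctr")
    out <- subtractPadded(core, lowComplexity, pad)
    out@name <- "ctr"
    out
}

#' Membership test for 1-based positions
#'
#' @param regions A \code{RegionSet}.
#' @param chrom,pos Parallel vectors; \code{pos} is 1-based.
#' @return Logical vector: \code{TRUE} where the (0-based) base
#'   \code{pos - 1} lies in some interval.
#' @export
inRegions <- function(regions, chrom, pos) {
    if (any(pos < 1)) stop("positions are 1-based; pos must be >= 1")
    if (!length(chrom)) return(logical())
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    GenomicRanges::countOverlaps(
        q, regionRanges(regions), ignore.strand = TRUE) > 0L
}

#' Enumerate all 1-based positions covered by a RegionSet
#'
#' @param regions A \code{RegionSet}.
#' @return \code{data.table(chrom, pos)} of every covered base.
#' @export
regionPositions <- function(regions) {
    gr <- regionRanges(regions)
    if (!length(gr)) return(data.table::data.table(chrom = character(),
                                                   pos = integer()))
    w <- GenomicRanges::width(gr)
    data.table::data.table(
        chrom = rep(as.character(GenomeInfoDb::seqnames(gr)), w),
        pos = unlist(lapply(seq_along(gr), function(i)
            seq.int(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))))
}

#' Read / write BED3
#'
#' BED files are 0-based half-open, tab-separated, without header; reading
#' then writing (or vice versa) reproduces the RegionSet exactly.
#'
#' @param path File path.
#' @param name Name for the resulting set (default: file base name).
#' @return \code{readBed} returns a \code{RegionSet}; \code{writeBed}
#'   invisibly returns \code{path}.
#' @export
readBed <- function(path, name = sub("\\.bed$", "", basename(path))) {
    gr <- rtracklayer::import(path, format = "bed")
    asRegionSet(gr, name)
}

#' @rdname readBed
#' @param regions A \code{RegionSet} to write.
#' @export
writeBed <- function(regions, path) {
    rtracklayer::export(regionRanges(regions), path, format = "bed")
    invisible(path)
}
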