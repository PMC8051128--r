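#' Normalise variant representations to minimal form
#'
#' Reduces each (chrom, pos, ref, alt) to its minimal representation: any
#' shared suffix is trimmed, then any shared prefix is trimmed (advancing
#' \code{pos}) leaving a single anchor base for indels.  Alleles are
#' upper-cased.  Full left-alignment through repeat tracts additionally
#' requires the reference sequence and is out of scope here; call sets
#' produced by the synthetic cohort generator are already minimal.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing variants
#'   (\code{pos} 1-based).
#' @return \code{data.table(chrom, pos, ref, alt, key)} with \code{key}
#'   the canonical \code{"chrom:pos:ref:alt"} string.
#' @examples
#' normalizeVariant("chr1", 100, "CTT", "CT")   # -> chr1:100 CT>C
#' @export
normalizeVariant <- function(chrom, pos, ref, alt) {
    ref <- toupper(ref); alt <- toupper(alt)
    pos <- as.integer(pos)
    n <- length(ref)
    stopifnot(length(chrom) == n, length(pos) == n, length(alt) == n)
    for (i in seq_len(n)) {
        r <- ref[i]; a <- alt[i]
        if (r == a) stop("ref and alt must differ (variant ", i, ")")
        ## trim shared suffix
        while (nchar(r) > 1L && nchar(a) > 1L &&
               substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
            r <- substr(r, 1L, nchar(r) - 1L)
            a <- substr(a, 1L, nchar(a) - 1L)
        }
        ## trim shared prefix, keeping one anchor base
        while (nchar(r) > 1L && nchar(a) > 1L &&
               substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
            r <- substr(r, 2L, nchar(r))
            a <- substr(a, 2L, nchar(a))
            pos[i] <- pos[i] + 1L
        }
        if (r == a) stop("degenerate variant at index ", i)
        ref[i] <- r; alt[i] <- a
    }
    out <- data.table::data.table(chrom = chrom, pos = pos, ref = ref,
                                  alt = alt)
    out$key <- paste(chrom, pos, ref, alt, sep = ":")
    out
}

#' Canonical variant key strings
#'
#' @inheritParams normalizeVariant
#' @return Character vector \code{"chrom:pos:ref:alt"} after
#'   normalisation.
#' @export
variantKey <- function(chrom, pos, ref, alt) {
    normalizeVariant(chrom, pos, ref, alt)$key
}

#' Split variant keys back into fields
#'
#' @param keys Character vector of \code{"chrom:pos:ref:alt"} keys.
#' @return \code{data.table(chrom, pos, ref, alt, key)}.
#' @export
parseVariantKey <- function(keys) {
    if (!length(keys)) {
        out <- data.table::data.table(chrom = character(), pos = integer(),
                                      ref = character(), alt = character())
        out$key <- character()
        return(out)
    }
    parts <- data.table::tstrsplit(keys, ":", fixed = TRUE)
    out <- data.table::data.table(chrom = parts[[1L]],
                                  pos = as.integer(parts[[2L]]),
                                  ref = parts[[3L]], alt = parts[[4L]])
    out$key <- keys
    out
}

.emptyCalls <- function() {
    out <- data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character())
    out$key <- character()
    out$vaf <- numeric()
    out
}

## TRUE for keys whose ref or alt allele is longer than one base.
isIndelKey <- function(keys) {
    p <- parseVariantKey(keys)
    nchar(p$ref) > 1L | nchar(p$alt) > 1L
}

#' Write a call set as minimal VCF 4.2
#'
#' One file per pipeline-library-combination and cell line, with the
#' reported VAF in the INFO field.  Columns beyond the fixed eight are not
#' emitted.
#'
#' @param calls \code{data.frame} with columns \code{chrom, pos, ref, alt,
#'   vaf}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCallsVcf <- function(calls, path) {
    calls <- data.table::as.data.table(calls)
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- if (nrow(calls)) {
        ord <- order(calls$chrom, calls$pos)
        with(calls[ord], sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tVAF=%.6g",
                                 chrom, as.integer(pos), ref, alt, vaf))
    } else character()
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a call-set VCF
#'
#' Reads a VCF (via \pkg{VariantAnnotation}) and returns normalised calls
#' with the VAF taken from the \code{VAF} INFO field when present.
#'
#' @param path VCF path.
#' @return \code{data.table(chrom, pos, ref, alt, key, vaf)}.
#' @export
readCallsVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    if (!length(rr))
        return(.emptyCalls())
    alts <- vapply(VariantAnnotation::alt(vcf), function(a)
        as.character(a)[1L], character(1))
    out <- normalizeVariant(
        chrom = as.character(GenomeInfoDb::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = alts)
    info <- VariantAnnotation::info(vcf)
    out$vaf <- if ("VAF" %in% names(info)) as.numeric(info$VAF) else NA_real_
    out[]
}
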