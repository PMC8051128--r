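## Synthetic cohort generator: a miniature in-silico analog of a pooled
## ten-cancer-cell-line reference study, with known ground truth at every
## downstream stage.  The genome is a handful of contigs totalling ~1 Mb;
## germline sharing follows a two-class population-frequency spectrum;
## each cancer line carries private germline and somatic variants and
## copy-number-altered segments; one line is tetraploid; one line is
## deliberately contaminated by another.

#' Cohort generator configuration
#'
#' Defaults emulate the study design this package models: ten diverse
#' cancer cell lines plus a normal diluent line B, pooled at equal DNA
#' mass; per-line CNA burdens taken from the published cohort table; a
#' tetraploid line (TLY); and the original-BLY:TLY = 2:1 contamination
#' event (massRatio 0.5 contaminant:host).
#'
#' @param contigs Named integer vector of contig lengths (default 3
#'   contigs, 1 Mb total).
#' @param lineIds Cancer line ids (default the ten study lines).
#' @param normalId Normal line id (default \code{"B"}); not pooled.
#' @param tetraploidLine Line with base ploidy 4 (default \code{"TLY"}).
#' @param cnaFraction Named numeric: target fraction of genome under CNA
#'   per line.
#' @param sharedCommon,sharedRare Numbers of shared germline loci at
#'   population frequencies \code{commonFreq} / \code{rareFreq}.
#' @param commonFreq,rareFreq The two-class frequency spectrum
#'   (defaults 0.3 and 0.01).
#' @param privateHetPerLine,privateHomPerLine Private germline variant
#'   counts per line (also used for the normal line).
#' @param somaticPerLine,somaticTly Somatic variant counts (the
#'   tetraploid line carries by far the most).
#' @param indelFraction Fraction of variants generated as short indels.
#' @param contamination \code{list(host=, contaminant=, massRatio=)} or
#'   \code{NULL}.
#' @param kitRosters Named list: WES kit id -> PLC id vector; plus
#'   \code{WGS1} -> WGS caller ids.
#' @param exonLength,exonSpacing Coding-exon geometry (bases).
#' @param kitDropout Per-kit probability of missing a coding exon.
#' @param hcHoleRate,hcHoleLength High-confidence-set hole geometry
#'   (expected holes per Mb; mean hole length).
#' @param lowComplexityRate,lowComplexityLength Low-complexity interval
#'   geometry (per Mb; mean length).
#' @param cosmicFraction Fraction of coding exons labelled COSMIC.
#' @param poolMassFractions Optional named numeric (one entry per pooled
#'   line, summing to 1) overriding the default equal-mass recipe.
#' @return A list with class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(
    contigs = c(ctgA = 400000L, ctgB = 350000L, ctgC = 250000L),
    lineIds = c("BLY", "BRA", "BRE", "CRV", "LIP", "LIV", "MAC", "SKN",
                "TES", "TLY"),
    normalId = "B",
    tetraploidLine = "TLY",
    cnaFraction = c(B = 0, BLY = 0.25, BRA = 0.90, BRE = 0.60, CRV = 0.70,
                    LIP = 0.90, LIV = 0.27, MAC = 0.80, SKN = 0.24,
                    TES = 0.72, TLY = 0.22),
    sharedCommon = 250L, sharedRare = 250L,
    commonFreq = 0.3, rareFreq = 0.01,
    privateHetPerLine = 120L, privateHomPerLine = 40L,
    somaticPerLine = 40L, somaticTly = 240L,
    indelFraction = 0.015,
    contamination = list(host = "BLY", contaminant = "TLY",
                         massRatio = 0.5),
    kitRosters = list(
        WES1 = paste0("plc", 1:8, ".WES1"),
        WES2 = paste0("plc", 1:8, ".WES2"),
        WES3 = paste0("plc", 1:7, ".WES3"),
        WES4 = paste0("plc", 1:3, ".WES4"),
        WGS1 = c("wgsA", "wgsB")),
    exonLength = 160L, exonSpacing = 450L,
    kitDropout = 0.05,
    hcHoleRate = 25, hcHoleLength = 2000L,
    lowComplexityRate = 150, lowComplexityLength = 25L,
    cosmicFraction = 0.3,
    poolMassFractions = NULL) {
    if (!is.null(poolMassFractions)) {
        if (!setequal(names(poolMassFractions), lineIds))
            stop("poolMassFractions must name exactly the pooled lines")
        if (abs(sum(poolMassFractions) - 1) > 1e-9)
            stop("poolMassFractions must sum to 1")
    }
    if (!is.null(contamination)) {
        if (!all(c(contamination$host, contamination$contaminant) %in% lineIds))
            stop("contamination references unknown line id")
        .assertPositive(contamination$massRatio, "contamination massRatio")
    }
    allIds <- c(lineIds, normalId)
    if (!all(allIds %in% names(cnaFraction)))
        stop("cnaFraction must name every line")
    structure(as.list(environment()), class = "cohortConfig")
}

## random DNA bases
.randBase <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.randAlt <- function(ref) {
    vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"),
                                           substr(r, 1L, 1L)), 1L),
           character(1), USE.NAMES = FALSE)
}

## Random interval set on the cohort contigs.
.randomIntervals <- function(contigs, n, meanLen, name) {
    chrom <- sample(names(contigs), n, replace = TRUE,
                    prob = contigs / sum(contigs))
    len <- pmax(5L, stats::rpois(n, meanLen))
    start <- vapply(seq_len(n), function(i)
        sample.int(max(1L, contigs[[chrom[i]]] - len[i]), 1L) - 1L, integer(1))
    RegionSet(chrom, start, start + len, name = name)
}

## Coding exons: regular tiling with jittered lengths.
.makeCoding <- function(contigs, exonLength, exonSpacing) {
    chroms <- character(); starts <- integer(); ends <- integer()
    for (ch in names(contigs)) {
        s <- seq.int(200L, contigs[[ch]] - 2L * exonSpacing, by = exonSpacing)
        len <- pmax(60L, stats::rpois(length(s), exonLength))
        chroms <- c(chroms, rep(ch, length(s)))
        starts <- c(starts, s)
        ends <- c(ends, s + len)
    }
    list(chrom = chroms, start = starts, end = ends)
}

#' Generate a synthetic cohort with ground truth
#'
#' Builds the region sets (kit designs, coding, high-confidence,
#' low-complexity, COSMIC, consensus target region), the per-line
#' genotype and CNA profiles, the contamination event, and the expected
#' pooled-sample VAF of every variant (computed with
#' \code{\link{expectedPoolVaf}} on the same profiles, so truth and model
#' are consistent by construction).
#'
#' @param config A \code{\link{cohortConfig}}.
#' @param seed Master seed; all randomness fans out deterministically.
#' @return A \code{\linkS4class{CohortTruth}}.
#' @export
generateCohort <- function(config = cohortConfig(), seed = 1L) {
    stopifnot(inherits(config, "cohortConfig"))
    seeds <- fanOutSeeds(seed, 4L)
    cfg <- config
    contigs <- cfg$contigs
    totalMb <- sum(contigs) / 1e6

    ## ---- region sets ----------------------------------------------------
    regions <- withSeed(seeds[1L], {
        exons <- .makeCoding(contigs, cfg$exonLength, cfg$exonSpacing)
        coding <- RegionSet(exons$chrom, exons$start, exons$end, "coding")
        nEx <- length(exons$chrom)
        kits <- list()
        for (kit in setdiff(names(cfg$kitRosters), "WGS1")) {
            keep <- stats::runif(nEx) > cfg$kitDropout
            kits[[kit]] <- RegionSet(exons$chrom[keep],
                                     pmax(0L, exons$start[keep] - 50L),
                                     exons$end[keep] + 50L, kit)
        }
        hc <- lapply(paste0("HG", 2:5), function(nm) {
            holes <- .randomIntervals(contigs, round(cfg$hcHoleRate * totalMb),
                                      cfg$hcHoleLength, "holes")
            genome <- RegionSet(names(contigs), rep(0L, length(contigs)),
                                unname(contigs), nm)
            out <- subtractPadded(genome, holes, 0L)
            out@name <- nm
            out
        })
        lowc <- .randomIntervals(contigs,
                                 round(cfg$lowComplexityRate * totalMb),
                                 cfg$lowComplexityLength, "lowComplexity")
        cosmicKeep <- stats::runif(nEx) < cfg$cosmicFraction
        cosmic <- RegionSet(exons$chrom[cosmicKeep], exons$start[cosmicKeep],
                            exons$end[cosmicKeep], "cosmic")
        genome <- RegionSet(names(contigs), rep(0L, length(contigs)),
                            unname(contigs), "genome")
        list(kits = kits, coding = coding, hc = hc, lowComplexity = lowc,
             cosmic = cosmic, genome = genome)
    })
    ctr <- buildCtr(regions$kits, regions$coding, regions$hc,
                    regions$lowComplexity, pad = 5L)
    cosmicHcCoding <- intersectAll(c(list(regions$cosmic, regions$coding),
                                     regions$hc), "cosmicHcCoding")

    allIds <- c(cfg$lineIds, cfg$normalId)

    ## ---- CNA segments ---------------------------------------------------
    cnaByLine <- withSeed(seeds[2L], {
        out <- list()
        for (id in allIds) {
            frac <- cfg$cnaFraction[[id]]
            ploidy <- if (id == cfg$tetraploidLine) 4L else 2L
            segs <- GenomicRanges::GRanges()
            if (frac > 0) {
                ## partition each contig into random 20-80 kb tiles, then
                ## draw shuffled tiles until the target span is altered
                tiles <- list()
                for (ch in names(contigs)) {
                    bp <- 1L
                    while (bp < contigs[[ch]]) {
                        len <- round(stats::runif(1L, 20000, 80000))
                        end <- min(bp + len - 1L, contigs[[ch]])
                        tiles[[length(tiles) + 1L]] <- c(ch, bp, end)
                        bp <- end + 1L
                    }
                }
                ordTiles <- sample(tiles)
                target <- frac * sum(contigs)
                got <- 0; takeN <- 0L
                while (got < target && takeN < length(ordTiles)) {
                    takeN <- takeN + 1L
                    t <- ordTiles[[takeN]]
                    got <- got + as.integer(t[3L]) - as.integer(t[2L]) + 1L
                }
                taken <- ordTiles[seq_len(takeN)]
                cn <- if (ploidy == 4L) sample(c(2L, 3L, 6L), takeN, TRUE,
                                               prob = c(.4, .3, .3))
                      else sample(c(1L, 3L, 4L), takeN, TRUE,
                                  prob = c(.4, .4, .2))
                segs <- GenomicRanges::GRanges(
                    vapply(taken, `[`, character(1), 1L),
                    IRanges::IRanges(as.integer(vapply(taken, `[`, character(1), 2L)),
                                     as.integer(vapply(taken, `[`, character(1), 3L))))
                S4Vectors::mcols(segs)$cn <- cn
                segs <- GenomicRanges::sort(segs)
            }
            out[[id]] <- segs
        }
        out
    })

    ## ---- variant loci and genotypes ------------------------------------
    geno <- withSeed(seeds[3L], {
        codingPos <- regionPositions(regions$coding)
        nShared <- cfg$sharedCommon + cfg$sharedRare
        nPriv <- (length(allIds)) * (cfg$privateHetPerLine + cfg$privateHomPerLine)
        nSom <- cfg$somaticPerLine * (length(cfg$lineIds) - 1L) + cfg$somaticTly
        nTot <- nShared + nPriv + nSom
        if (nTot > nrow(codingPos)) stop("genome too small for variant counts")
        pick <- codingPos[sample.int(nrow(codingPos), nTot)]
        isIndel <- stats::runif(nTot) < cfg$indelFraction
        ref <- .randBase(nTot); alt <- .randAlt(ref)
        if (any(isIndel)) {
            idx <- which(isIndel)
            extra <- vapply(idx, function(i)
                paste(.randBase(sample(1:3, 1L)), collapse = ""), character(1))
            del <- stats::runif(length(idx)) < 0.5
            ref[idx[del]] <- paste0(ref[idx[del]], extra[del])
            alt[idx[del]] <- substr(ref[idx[del]], 1L, 1L)
            alt[idx[!del]] <- paste0(ref[idx[!del]], extra[!del])
        }
        loci <- data.table::data.table(chrom = pick$chrom, pos = pick$pos,
                                       ref = ref, alt = alt)
        loci$key <- paste(loci$chrom, loci$pos, loci$ref, loci$alt, sep = ":")
        ## partition loci
        i <- 0L
        take <- function(n) {
            if (n == 0L) return(loci[0L])
            out <- loci[(i + 1L):(i + n)]; i <<- i + n; out
        }
        shared <- take(nShared)
        shared$freq <- rep(c(cfg$commonFreq, cfg$rareFreq),
                           c(cfg$sharedCommon, cfg$sharedRare))
        priv <- list(); som <- list()
        for (id in allIds) {
            ph <- take(cfg$privateHetPerLine); ph$dosage <- 1L
            pm <- take(cfg$privateHomPerLine); pm$dosage <- 2L
            priv[[id]] <- rbind(ph, pm)
        }
        for (id in cfg$lineIds) {
            n <- if (id == cfg$tetraploidLine) cfg$somaticTly else cfg$somaticPerLine
            som[[id]] <- take(n)
        }
        ## genotype assembly per line
        mkGeno <- function(id) {
            ploidy <- if (id == cfg$tetraploidLine) 4L else 2L
            rows <- list()
            ## shared germline: founder dosage ~ Binom(2, freq)
            d <- stats::rbinom(nrow(shared), 2L, shared$freq)
            carry <- shared[d > 0L]
            if (nrow(carry)) { carry$dosage <- d[d > 0L]; rows$shared <- carry }
            pv <- priv[[id]]
            rows$priv <- pv
            germ <- data.table::rbindlist(rows, fill = TRUE)
            germ <- germ[, c("chrom", "pos", "ref", "alt", "key", "dosage"),
                         with = FALSE]
            germ$somatic <- FALSE
            sm <- if (id %in% names(som)) som[[id]] else NULL
            if (!is.null(sm) && nrow(sm)) {
                sm <- sm[, c("chrom", "pos", "ref", "alt", "key"), with = FALSE]
                sm$dosage <- NA_integer_  # somatic: one mutated copy
                sm$somatic <- TRUE
                germ <- rbind(germ, sm)
            }
            ## local copy number and alt copies
            cnProbe <- new("CellLineProfile", lineId = id, massFraction = 0,
                           basePloidy = as.integer(ploidy),
                           cnaSegments = cnaByLine[[id]],
                           genotypes = .emptyGenotypes(),
                           contamination = NULL)
            cn <- cnAtPositions(cnProbe, germ$chrom, germ$pos)
            frac <- ifelse(germ$somatic, NA_real_, germ$dosage / 2)
            raw <- cn * frac
            lo <- floor(raw)
            altCopies <- as.integer(lo + (stats::runif(nrow(germ)) < (raw - lo)))
            altCopies[germ$somatic] <- 1L  # somatic hits exactly one copy
            keep <- altCopies > 0L & cn > 0L
            out <- data.table::data.table(
                chrom = germ$chrom, pos = germ$pos, ref = germ$ref,
                alt = germ$alt,
                altCopies = as.integer(pmin(altCopies, cn)),
                totalCopies = cn, somatic = germ$somatic)
            out$key <- germ$key
            data.table::setcolorder(out, c("chrom", "pos", "ref", "alt",
                                           "key", "altCopies", "totalCopies",
                                           "somatic"))
            out[keep]
        }
        lapply(stats::setNames(allIds, allIds), mkGeno)
    })

    ## ---- profiles -------------------------------------------------------
    nPool <- length(cfg$lineIds)
    recipe <- if (is.null(cfg$poolMassFractions))
        stats::setNames(rep(1 / nPool, nPool), cfg$lineIds)
    else cfg$poolMassFractions[cfg$lineIds]
    profiles <- list()
    for (id in allIds) {
        ploidy <- if (id == cfg$tetraploidLine) 4L else 2L
        contam <- NULL
        if (!is.null(cfg$contamination) && id == cfg$contamination$host)
            contam <- list(otherLineId = cfg$contamination$contaminant,
                           massRatio = cfg$contamination$massRatio)
        profiles[[id]] <- new("CellLineProfile", lineId = id,
                              massFraction = if (id %in% cfg$lineIds)
                                  unname(recipe[[id]]) else 0,
                              basePloidy = as.integer(ploidy),
                              cnaSegments = cnaByLine[[id]],
                              genotypes = geno[[id]],
                              contamination = contam)
    }
    truth <- .poolVafTable(profiles, recipe)

    new("CohortTruth", lines = profiles, poolRecipe = recipe,
        truePoolVaf = truth,
        regionFiles = c(regions$kits,
                        list(coding = regions$coding,
                             lowComplexity = regions$lowComplexity,
                             cosmic = regions$cosmic,
                             cosmicHcCoding = cosmicHcCoding,
                             genome = regions$genome, ctr = ctr),
                        stats::setNames(regions$hc,
                                        paste0("hc", seq_along(regions$hc)))),
        contigs = contigs, kitRosters = cfg$kitRosters)
}

.emptyGenotypes <- function() {
    out <- data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  altCopies = integer(),
                                  totalCopies = integer(),
                                  somatic = logical())
    out$key <- character()
    data.table::setcolorder(out, c("chrom", "pos", "ref", "alt", "key",
                                   "altCopies", "totalCopies", "somatic"))
    out
}
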