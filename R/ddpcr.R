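## Droplet digital PCR: Poisson occupancy model, allele concentration and
## VAF estimation with delta-method intervals, occupancy-consistency QC,
## stratified target selection and verification verdicts.

#' Combine replicate ddPCR wells by summing droplet counts
#'
#' Count summation (not VAF averaging) preserves the sufficient
#' statistic of the Poisson occupancy model.
#'
#' @param wells List of \code{\linkS4class{DdpcrWell}} for the same assay
#'   and sample.
#' @return A single combined \code{DdpcrWell}.
#' @export
combineWells <- function(wells) {
    stopifnot(length(wells) >= 1L)
    w1 <- wells[[1L]]
    new("DdpcrWell", assayId = w1@assayId, sampleId = w1@sampleId,
        nTotal = sum(vapply(wells, slot, numeric(1), "nTotal")),
        nDoubleNeg = sum(vapply(wells, slot, numeric(1), "nDoubleNeg")),
        nRefOnly = sum(vapply(wells, slot, numeric(1), "nRefOnly")),
        nAltOnly = sum(vapply(wells, slot, numeric(1), "nAltOnly")),
        nDoublePos = sum(vapply(wells, slot, numeric(1), "nDoublePos")),
        inputMassNg = sum(vapply(wells, slot, numeric(1), "inputMassNg")))
}

#' Per-allele mean occupancy from droplet counts
#'
#' Under Poisson partitioning the zero-class closed form gives
#' \code{lambda = -log(fraction of droplets negative for the allele)},
#' where negative-for-ref droplets are double-negative plus alt-only and
#' negative-for-alt droplets are double-negative plus ref-only.
#'
#' @param well A \code{\linkS4class{DdpcrWell}}.
#' @return Named numeric \code{c(lambdaRef, lambdaAlt)}.
#' @export
alleleConcentration <- function(well) {
    if (well@nTotal <= 0) stop("empty well")
    negRef <- well@nDoubleNeg + well@nAltOnly
    negAlt <- well@nDoubleNeg + well@nRefOnly
    if (negRef == 0 || negAlt == 0)
        stop("zero negative droplets for an allele: well saturated")
    c(lambdaRef = -log(negRef / well@nTotal),
      lambdaAlt = -log(negAlt / well@nTotal))
}

#' ddPCR VAF estimate with a delta-method interval
#'
#' \code{vaf = lambdaAlt / (lambdaRef + lambdaAlt)}.  The 95\% interval
#' propagates the binomial uncertainty of the two negative-droplet
#' fractions through the log transform.
#'
#' @param well A \code{\linkS4class{DdpcrWell}}.
#' @param conf Confidence level (default 0.95).
#' @return List: \code{vaf}, \code{ci} (length-2), \code{lambdaRef},
#'   \code{lambdaAlt}.
#' @export
ddpcrVaf <- function(well, conf = 0.95) {
    lam <- alleleConcentration(well)
    lr <- lam[["lambdaRef"]]; la <- lam[["lambdaAlt"]]
    if (lr + la == 0)
        return(list(vaf = NA_real_, ci = c(NA_real_, NA_real_),
                    lambdaRef = lr, lambdaAlt = la, flagged = TRUE))
    n <- well@nTotal
    qr <- exp(-lr); qa <- exp(-la)
    ## var(lambda) = (1-q) / (n q) from the binomial negative fraction
    vlr <- (1 - qr) / (n * qr)
    vla <- (1 - qa) / (n * qa)
    vaf <- la / (lr + la)
    grLr <- -la / (lr + la)^2
    grLa <- lr / (lr + la)^2
    se <- sqrt(grLr^2 * vlr + grLa^2 * vla)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    list(vaf = vaf, ci = c(max(0, vaf - z * se), min(1, vaf + z * se)),
         lambdaRef = lr, lambdaAlt = la, flagged = FALSE)
}

#' Occupancy-consistency QC of a ddPCR well
#'
#' Compares the observed four-way droplet counts with the expectation
#' under independent occupancy of the two alleles (e.g. expected
#' double-positives \code{n (1 - exp(-lambdaRef)) (1 - exp(-lambdaAlt))})
#' via a Pearson chi-square statistic with 1 degree of freedom (four
#' cells, two estimated marginal occupancies).  Wells not achieving the
#' expected distributional frequencies fail QC.
#'
#' @param well A \code{\linkS4class{DdpcrWell}}.
#' @param alpha Significance level (default 0.01).
#' @return List: \code{pass}, \code{statistic}, \code{pValue},
#'   \code{collapsed} (TRUE when an expected cell count below 1 forced a
#'   2-cell collapse on the alt margin).
#' @export
occupancyConsistency <- function(well, alpha = 0.01) {
    n <- well@nTotal
    negRef <- well@nDoubleNeg + well@nAltOnly
    negAlt <- well@nDoubleNeg + well@nRefOnly
    qr <- negRef / n; qa <- negAlt / n
    obs <- c(well@nDoubleNeg, well@nRefOnly, well@nAltOnly, well@nDoublePos)
    expd <- n * c(qr * qa, (1 - qr) * qa, qr * (1 - qa), (1 - qr) * (1 - qa))
    collapsed <- FALSE
    if (any(expd < 1)) {
        ## collapse the alt margin: compare alt-positive split by ref only
        obs <- c(obs[1L] + obs[3L], obs[2L] + obs[4L])
        expd <- c(expd[1L] + expd[3L], expd[2L] + expd[4L])
        collapsed <- TRUE
    }
    keep <- expd > 0
    stat <- sum((obs[keep] - expd[keep])^2 / expd[keep])
    df <- if (collapsed) 1L else 1L  # 4 cells - 1 - 2 estimated margins
    p <- if (collapsed && length(obs) == 2L) 1 else
        stats::pchisq(stat, df = df, lower.tail = FALSE)
    list(pass = p >= alpha, statistic = stat, pValue = p,
         collapsed = collapsed)
}

#' Stratified random target selection plan
#'
#' @param categories List of \code{list(name=, quota=, filter=)} where
#'   \code{filter} is a function of the candidate table returning a
#'   logical vector.
#' @param seed Selection seed (deterministic given seed).
#' @param proximityExclusionBp Candidates with another known variant
#'   within this many bases are excluded before sampling (default 30).
#' @return A list with class \code{"selectionPlan"}.
#' @export
selectionPlan <- function(categories, seed = 1L, proximityExclusionBp = 30L) {
    structure(list(categories = categories, seed = seed,
                   proximityExclusionBp = proximityExclusionBp),
              class = "selectionPlan")
}

#' Stratified random selection of ddPCR assay targets
#'
#' Per category: the candidate pool is filtered, candidates with a
#' close-by known variant are removed (they would interfere with primer
#' or probe), and the quota is drawn uniformly without replacement.
#'
#' @param candidates \code{data.frame} of annotated truth-set records
#'   with at least \code{key, chrom, pos}.
#' @param plan A \code{\link{selectionPlan}}.
#' @param allVariants Optional \code{data.frame(chrom, pos)} of all known
#'   variants for the proximity filter (default: the candidates
#'   themselves).
#' @return \code{data.table} of selected targets with a \code{category}
#'   column.
#' @export
selectTargets <- function(candidates, plan, allVariants = candidates) {
    candidates <- data.table::as.data.table(candidates)
    allVariants <- data.table::as.data.table(allVariants)
    prox <- plan$proximityExclusionBp
    hasNeighbour <- vapply(seq_len(nrow(candidates)), function(i) {
        ch <- candidates$chrom[i]; p <- candidates$pos[i]
        any(allVariants$chrom == ch & abs(allVariants$pos - p) <= prox &
            !(allVariants$pos == p))
    }, logical(1))
    eligible <- candidates[!hasNeighbour]
    withSeed(plan$seed, {
        out <- list()
        for (cat in plan$categories) {
            pool <- eligible[cat$filter(eligible)]
            if (cat$quota > nrow(pool))
                stop("quota ", cat$quota, " exceeds pool size ", nrow(pool),
                     " in category '", cat$name, "'")
            sel <- pool[sample.int(nrow(pool), cat$quota)]
            sel$category <- cat$name
            out[[cat$name]] <- sel
        }
        data.table::rbindlist(out)
    })
}

#' Verification verdict for one assay across samples
#'
#' Replicate wells are combined by count summation; each combined well
#' must pass occupancy QC.  The verdict is \code{verified_positive} when
#' the ddPCR VAF in every expected-positive sample exceeds the background
#' floor and its interval overlaps the WES binomial interval;
#' \code{verified_negative} when all expected-negative samples are below
#' the floor; \code{discordant} when detection disagrees with the WES
#' estimate; \code{failed_qc} when occupancy consistency fails.
#'
#' @param wells List of \code{\linkS4class{DdpcrWell}} (any mix of
#'   samples/replicates for one assay).
#' @param wesVaf Named list: sample id -> \code{list(vaf=, dp=, adp=)}
#'   (counts used for the exact binomial interval) for expected-positive
#'   samples.
#' @param expectedPositive,expectedNegative Character vectors of sample
#'   ids.
#' @param floor ddPCR background floor (default 0.001, i.e. 0.1\% VAF:
#'   assay noise below this is uninformative).
#' @param qcAlpha Occupancy-consistency alpha (default 0.01).
#' @param ciAlpha Alpha for the two overlap intervals (default 0.01).
#' @return A list with class \code{"ddpcrVerdict"}: \code{assayId},
#'   \code{status}, \code{vafDdpcr}, \code{vafWes}, \code{perSample}.
#' @export
verifyAssay <- function(wells, wesVaf, expectedPositive,
                        expectedNegative = character(), floor = 0.001,
                        qcAlpha = 0.01, ciAlpha = 0.01) {
    assayId <- wells[[1L]]@assayId
    bySample <- split(wells, vapply(wells, slot, character(1), "sampleId"))
    combined <- lapply(bySample, combineWells)
    missingPos <- setdiff(expectedPositive, names(combined))
    if (length(missingPos))
        return(structure(list(assayId = assayId, status = "incomplete",
                              vafDdpcr = NA_real_, vafWes = NA_real_,
                              perSample = NULL,
                              missing = missingPos),
                         class = "ddpcrVerdict"))
    perSample <- lapply(combined, function(w) {
        qc <- occupancyConsistency(w, qcAlpha)
        est <- ddpcrVaf(w, conf = 1 - ciAlpha)
        list(qcPass = qc$pass, vaf = est$vaf, ci = est$ci)
    })
    if (!all(vapply(perSample, `[[`, logical(1), "qcPass")))
        return(structure(list(assayId = assayId, status = "failed_qc",
                              vafDdpcr = NA_real_, vafWes = NA_real_,
                              perSample = perSample),
                         class = "ddpcrVerdict"))
    posOk <- TRUE; discord <- FALSE
    vafD <- NA_real_; vafW <- NA_real_
    for (s in expectedPositive) {
        est <- perSample[[s]]
        vafD <- est$vaf
        wes <- wesVaf[[s]]
        if (is.null(wes)) { posOk <- FALSE; next }
        vafW <- wes$vaf
        wci <- if (!is.null(wes$dp) && wes$dp > 0)
            .clopperPearson(wes$adp, wes$dp, 1 - ciAlpha)
        else c(wes$vaf - 0.02, wes$vaf + 0.02)
        overlap <- est$ci[1L] <= wci[2L] && wci[1L] <= est$ci[2L]
        if (est$vaf <= floor) posOk <- FALSE
        else if (!overlap) discord <- TRUE
    }
    negBelow <- all(vapply(expectedNegative, function(s) {
        est <- perSample[[s]]
        !is.null(est) && est$vaf < floor
    }, logical(1)))
    status <- if (length(expectedPositive)) {
        if (discord) "discordant"
        else if (posOk) "verified_positive"
        else "discordant"
    } else if (length(expectedNegative)) {
        if (negBelow) "verified_negative" else "discordant"
    } else "incomplete"
    structure(list(assayId = assayId, status = status, vafDdpcr = vafD,
                   vafWes = vafW, perSample = perSample),
              class = "ddpcrVerdict")
}
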