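## Builders for hand-crafted cell line profiles.
mkProfile <- function(id, mass, ploidy = 2L, genotypes = NULL, cna = NULL,
                      contamination = NULL) {
    g <- if (is.null(genotypes)) pooltruth:::.emptyGenotypes() else genotypes
    new("CellLineProfile", lineId = id, massFraction = mass,
        basePloidy = as.integer(ploidy),
        cnaSegments = if (is.null(cna)) GenomicRanges::GRanges() else cna,
        genotypes = g, contamination = contamination)
}

mkGenotype <- function(chrom, pos, ref, alt, altCopies, totalCopies,
                       somatic = FALSE) {
    out <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                                  ref = ref, alt = alt,
                                  altCopies = as.integer(altCopies),
                                  totalCopies = as.integer(totalCopies),
                                  somatic = somatic)
    out$key <- paste(chrom, pos, ref, alt, sep = ":")
    data.table::setcolorder(out, c("chrom", "pos", "ref", "alt", "key",
                                   "altCopies", "totalCopies", "somatic"))
    out
}

tenLinePool <- function(altCopies) {
    carrier <- mkProfile("L1", 0.1,
                         genotypes = mkGenotype("c", 100, "A", "G",
                                                altCopies, 2))
    others <- lapply(2:10, function(i) mkProfile(paste0("L", i), 0.1))
    stats::setNames(c(list(carrier), others), paste0("L", 1:10))
}

test_that("pooled VAF of private variants in a ten-line equal-mass pool", {
    ## heterozygous private variant: 5%
    expect_equal(expectedPoolVaf(tenLinePool(1L), "c:100:A:G"), 0.05)
    ## homozygous private variant: 10%
    expect_equal(expectedPoolVaf(tenLinePool(2L), "c:100:A:G"), 0.10)
})

test_that("pooled VAF honours local copy number and genome equivalents", {
    ## one line cn=4 with 2 alt copies, nine diploid reference lines:
    ## (0.05*4*0.5) / (0.05*4 + 9*0.05*2) = 0.1 / 1.1
    lines <- tenLinePool(1L)
    lines$L1 <- mkProfile("L1", 0.1,
                          genotypes = mkGenotype("c", 100, "A", "G", 2, 4))
    expect_equal(expectedPoolVaf(lines, "c:100:A:G"), 0.1 / 1.1,
                 tolerance = 1e-12)
    ## single-line pool, homozygous variant: VAF 1
    solo <- list(L1 = mkProfile("L1", 1,
                                genotypes = mkGenotype("c", 1, "A", "T", 2, 2)))
    expect_equal(expectedPoolVaf(solo, "c:1:A:T"), 1.0)
    ## relabelling invariance
    lines2 <- lines[c(3, 1, 7, 2, 4:6, 8:10)]
    expect_equal(expectedPoolVaf(lines2, "c:100:A:G"),
                 expectedPoolVaf(lines, "c:100:A:G"))
    ## mass fraction -> 1 recovers the line's own allele fraction
    solo2 <- list(L1 = mkProfile("L1", 1,
                                 genotypes = mkGenotype("c", 9, "A", "T", 1, 2)))
    expect_equal(expectedPoolVaf(solo2, "c:9:A:T"), 0.5)
    ## no covering line is an error
    zero <- list(L1 = mkProfile("L1", 1, genotypes = mkGenotype(
        "c", 100, "A", "G", 0, 0)))
    expect_error(expectedPoolVaf(zero, "c:100:A:G"), "copy number")
    ## mass fractions must sum to 1
    expect_error(expectedPoolVaf(list(L1 = mkProfile("L1", 0.5)), "c:1:A:T"),
                 "sum to 1")
})

test_that("a 2:1 contaminant produces a 2/3 allele fraction in the host line", {
    ## variant private and homozygous in contaminant X, host Y clean;
    ## X:Y mass 2:1 inside the received "Y" DNA
    x <- mkProfile("X", 0, genotypes = mkGenotype("c", 50, "A", "G", 2, 2))
    y <- mkProfile("Y", 1, contamination = list(otherLineId = "X",
                                                massRatio = 2))
    tab <- pooltruth:::.poolVafTable(list(X = x, Y = y), c(Y = 1))
    expect_equal(tab$vaf[tab$key == "c:50:A:G"], 2 / 3, tolerance = 1e-12)
    ## unknown contaminant line id errors
    bad <- mkProfile("Z", 1, contamination = list(otherLineId = "missing",
                                                  massRatio = 1))
    expect_error(pooltruth:::.poolVafTable(list(Z = bad), c(Z = 1)),
                 "unknown line")
})

test_that("dilution arithmetic scales VAF by the mass mixing fraction", {
    ## 0.5% VAF in A, absent in B, 1:24 -> 0.02%
    expect_equal(expectedDilutionVaf(0.005, 1, 0, dilutionSpec(1, 24)),
                 0.0002)
    ## 1:1 halves
    expect_equal(expectedDilutionVaf(0.10, 1, 0, dilutionSpec(1, 1)), 0.05)
    ## germline fixed point: same VAF in A and B is unchanged
    expect_equal(expectedDilutionVaf(0.5, 1, 0.5, dilutionSpec(1, 4)), 0.5)
    ## pure diluent and identity dilutions
    expect_equal(expectedDilutionVaf(0.3, 1, 0, dilutionSpec(0, 1)), 0)
    expect_equal(expectedDilutionVaf(0.3, 1, 0, dilutionSpec(1, 0)), 0.3)
    ## linear in alpha when vafB = 0 and neutral copy number
    alphas <- seq(0.1, 0.9, by = 0.2)
    vals <- vapply(alphas, function(a)
        expectedDilutionVaf(0.2, 1, 0, dilutionSpec(a, 1 - a)), numeric(1))
    expect_equal(vals, 0.2 * alphas)
    ## strictly decreasing in the diluent parts
    v <- vapply(c(1, 4, 24, 99), function(b)
        expectedDilutionVaf(0.2, 1, 0, dilutionSpec(1, b)), numeric(1))
    expect_true(all(diff(v) < 0))
})

test_that("merged-count VAF estimation sums within groups and averages across kits", {
    counts <- data.table::data.table(
        libraryId = c("L1", "L2", "L3"), DP = c(200L, 200L, 200L),
        ADP = c(10L, 12L, 8L))
    est <- estimateVaf(counts, list(kit1 = c("L1", "L2", "L3")))
    expect_equal(est$groups$vaf, 30 / 600)
    expect_equal(est$final, 0.05)
    ## cross-kit final is the unweighted mean of per-kit merged estimates
    counts2 <- data.table::data.table(
        libraryId = c("A1", "B1", "C1"), DP = c(100L, 100L, 100L),
        ADP = c(4L, 5L, 6L))
    est2 <- estimateVaf(counts2, list(k1 = "A1", k2 = "B1", k3 = "C1"))
    expect_equal(est2$final, 0.05)
    ## saturated single library: vaf 1 with CI upper bound 1
    est3 <- estimateVaf(data.table::data.table(libraryId = "x", DP = 50L,
                                               ADP = 50L), list(g = "x"))
    expect_equal(est3$groups$vaf, 1)
    expect_equal(est3$groups$hi, 1)
    ## zero-depth group is flagged missing, not zero
    est4 <- estimateVaf(data.table::data.table(libraryId = "x", DP = 0L,
                                               ADP = 0L), list(g = "x"))
    expect_true(is.na(est4$groups$vaf))
})

test_that("VAF estimation from simulated pileups is unbiased", {
    co <- smallCohort()
    tv <- truePoolVaf(co)
    obs <- measuredVafs(co, "A", meanDepth = 200, nLibs = 2L, seed = 31L)
    m <- merge(obs, tv[, c("key", "vaf")], by = "key",
               suffixes = c("Obs", "True"))
    err <- m$vafObs - m$vafTrue
    se <- sqrt(mean(m$vafTrue * (1 - m$vafTrue)) / (400 * nrow(m)))
    expect_lt(abs(mean(err)), 2 * se + 1e-3)
})

test_that("concordance reproduces ordinary least squares", {
    x <- c(1, 2, 3, 4, 5)
    expect_equal(concordance(x, x)$rSquared, 1)
    expect_equal(concordance(x, x)$slope, 1)
    expect_equal(concordance(x, 2 * x)$slope, 2)
    expect_equal(concordance(x, 2 * x)$rSquared, 1)
    ## fixed 10-point fixture vs hand-computed OLS
    xf <- c(0.01, 0.02, 0.05, 0.08, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5)
    yf <- c(0.012, 0.018, 0.055, 0.074, 0.11, 0.148, 0.19, 0.31, 0.41, 0.48)
    fit <- concordance(xf, yf)
    sxy <- sum((xf - mean(xf)) * (yf - mean(yf)))
    sxx <- sum((xf - mean(xf))^2)
    beta <- sxy / sxx
    alphaHat <- mean(yf) - beta * mean(xf)
    r2 <- sxy^2 / (sxx * sum((yf - mean(yf))^2))
    expect_equal(fit$slope, beta, tolerance = 1e-10)
    expect_equal(fit$intercept, alphaHat, tolerance = 1e-10)
    expect_equal(fit$rSquared, r2, tolerance = 1e-10)
    ## log scale drops non-positive pairs and reports the count
    fitLog <- concordance(c(0, xf), c(0.001, yf), scale = "log10")
    expect_equal(fitLog$nDropped, 1L)
    expect_equal(fitLog$n, 10L)
    expect_error(concordance(rep(1, 5), 1:5), "variance")
})

test_that("mixture regression recovers pool fractions exactly without noise", {
    withr::with_seed(21, {
        nVar <- 40L
        lineIds <- paste0("L", 1:10)
        rows <- list()
        pool <- list()
        for (i in seq_along(lineIds)) {
            keys <- sprintf("c:%d:A:G", (i - 1L) * nVar + seq_len(nVar))
            vafs <- sample(c(0.5, 1.0), nVar, replace = TRUE)
            dtl <- data.table::data.table(lineId = lineIds[i], vaf = vafs)
            dtl$key <- keys
            rows[[i]] <- dtl
            dtp <- data.table::data.table(vaf = 0.1 * vafs)
            dtp$key <- keys
            pool[[i]] <- dtp
        }
        lineVafs <- data.table::rbindlist(rows)
        poolVafs <- data.table::rbindlist(pool)
        fit <- estimateMixture(poolVafs, lineVafs)
        expect_equal(unname(mixtureCoefficients(fit)), rep(0.1, 10),
                     tolerance = 1e-8)
        expect_lt(residualSd(fit), 1e-10)
        ## nonnegative variant agrees in the noise-free case
        fitNn <- estimateMixture(poolVafs, lineVafs, nonneg = TRUE)
        expect_equal(unname(mixtureCoefficients(fitNn)), rep(0.1, 10),
                     tolerance = 1e-6)
    })
})

test_that("mixture regression recovers random simplex fractions", {
    withr::with_seed(77, {
        for (rep in 1:5) {
            w <- stats::rgamma(4, 2); w <- w / sum(w)
            lineIds <- paste0("L", 1:4)
            rows <- list(); pool <- list()
            for (i in 1:4) {
                keys <- sprintf("c:%d:A:G", (i - 1L) * 30L + 1:30)
                vafs <- stats::runif(30, 0.3, 1)
                dtl <- data.table::data.table(lineId = lineIds[i], vaf = vafs)
                dtl$key <- keys
                rows[[i]] <- dtl
                dtp <- data.table::data.table(vaf = w[i] * vafs)
                dtp$key <- keys
                pool[[i]] <- dtp
            }
            fit <- estimateMixture(data.table::rbindlist(pool),
                                   data.table::rbindlist(rows))
            expect_lt(max(abs(mixtureCoefficients(fit) - w)), 0.01)
        }
    })
})

test_that("two-line 0.5/0.5 pools and rank deficiency behave as specified", {
    keys1 <- sprintf("c:%d:A:G", 1:10)
    keys2 <- sprintf("c:%d:A:G", 11:20)
    l1 <- data.table::data.table(lineId = "A", vaf = rep(0.5, 10)); l1$key <- keys1
    l2 <- data.table::data.table(lineId = "B", vaf = rep(0.5, 10)); l2$key <- keys2
    pool <- data.table::data.table(vaf = rep(0.25, 20))
    pool$key <- c(keys1, keys2)
    fit <- estimateMixture(pool, rbind(l1, l2))
    expect_equal(unname(mixtureCoefficients(fit)), c(0.5, 0.5))
    ## a line with all-zero design column is collinear -> error naming it
    l3 <- data.table::data.table(lineId = "C", vaf = rep(0, 10)); l3$key <- keys1
    expect_error(estimateMixture(pool, rbind(l1, l2, l3), subset = "all"),
                 "collinear")
})

test_that("contamination detection flags near-superset call profiles", {
    a <- sprintf("c:%d:A:G", 1:100)
    expect_true(detectContamination(list(X = a, Y = a))$flagged[1])
    res <- detectContamination(list(X = a, Y = sprintf("c:%d:A:G", 101:200)))
    expect_equal(res$variantOverlap, c(0, 0))
    expect_false(any(res$flagged))
    ## asymmetric: X subset of Y flags X->Y but not the reverse
    res2 <- detectContamination(list(X = a[1:50],
                                     Y = c(a, sprintf("c:%d:A:G", 300:399))))
    xy <- res2[res2$lineX == "X"]
    yx <- res2[res2$lineX == "Y"]
    expect_true(xy$flagged)
    expect_false(yx$flagged)
    expect_error(detectContamination(list(X = a)), "two lines")
})

test_that("the planted TLY-into-BLY contamination is detected across call-set seeds", {
    co <- smallCohort()
    roster <- co@kitRosters["WES1"]
    profs <- defaultPipelineProfiles(co)[roster$WES1]
    flagged <- 0L
    overlaps <- numeric()
    for (s in 1:10) {
        calls <- simulateCallsets(co, profs, lineIds = c("BLY", "TLY"),
                                  seed = 100L + s)
        cons <- wesKitConsensus(calls, roster)
        perLine <- split(cons$key, cons$lineId)
        res <- detectContamination(perLine)
        row <- res[res$lineX == "TLY" & res$lineY == "BLY"]
        overlaps <- c(overlaps, row$variantOverlap)
        if (row$flagged) flagged <- flagged + 1L
    }
    expect_gte(flagged, 9L)
    expect_gte(stats::median(overlaps), 0.90)
})
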