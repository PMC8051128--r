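mkCalls <- function(plcIds, lineId, key, vaf) {
    out <- data.table::data.table(plcId = plcIds, lineId = lineId, vaf = vaf)
    out$key <- key
    out
}

test_that("per-kit majority vote applies the half-roster and VAF rules", {
    roster8 <- paste0("p", 1:8)
    cfg <- consensusConfig()
    ## 4 of 8 at VAF 0.12: exactly half -> included
    calls <- mkCalls(paste0("p", 1:4), "LIV", "c:10:A:G", 0.12)
    expect_equal(voteClass1Kit(calls, roster8, cfg), "c:10:A:G")
    ## 3 of 7 fails (ceil(3.5) = 4), 4 of 7 passes
    roster7 <- paste0("p", 1:7)
    expect_length(voteClass1Kit(mkCalls(paste0("p", 1:3), "LIV",
                                        "c:10:A:G", 0.2), roster7, cfg), 0)
    expect_equal(voteClass1Kit(mkCalls(paste0("p", 1:4), "LIV",
                                       "c:10:A:G", 0.2), roster7, cfg),
                 "c:10:A:G")
    ## 5 of 8 but all below the 10% floor -> excluded
    expect_length(voteClass1Kit(mkCalls(paste0("p", 1:5), "LIV",
                                        "c:10:A:G", 0.08), roster8, cfg), 0)
    ## boundary: VAF exactly at the floor counts
    expect_equal(voteClass1Kit(mkCalls(paste0("p", 1:4), "LIV",
                                       "c:10:A:G", 0.10), roster8, cfg),
                 "c:10:A:G")
    ## votes must come from the same line
    split2 <- rbind(mkCalls(paste0("p", 1:2), "LIV", "c:10:A:G", 0.2),
                    mkCalls(paste0("p", 3:4), "TES", "c:10:A:G", 0.2))
    expect_length(voteClass1Kit(split2, roster8, cfg), 0)
    ## per-line winners are pooled across lines (union)
    u <- rbind(mkCalls(paste0("p", 1:4), "LIV", "c:10:A:G", 0.2),
               mkCalls(paste0("p", 1:4), "TES", "c:20:T:C", 0.2))
    expect_setequal(voteClass1Kit(u, roster8, cfg),
                    c("c:10:A:G", "c:20:T:C"))
    ## unknown PLC errors
    expect_error(voteClass1Kit(mkCalls("ghost", "LIV", "c:1:A:G", 0.5),
                               roster8, cfg), "roster")
})

test_that("voting is monotone in supporting calls and in the VAF floor", {
    withr::with_seed(19, {
        roster <- paste0("p", 1:9)
        keys <- sprintf("c:%d:A:G", 1:40)
        base <- data.table::rbindlist(lapply(keys, function(k) {
            n <- sample(0:9, 1L)
            if (n == 0) return(NULL)
            mkCalls(sample(roster, n), "L1", k, stats::runif(n, 0.05, 0.5))
        }))
        got <- voteClass1Kit(base, roster)
        ## adding one more supporting call never removes a winner
        extraKey <- keys[1L]
        plcUsed <- base$plcId[base$key == extraKey]
        free <- setdiff(roster, plcUsed)
        if (length(free)) {
            more <- rbind(base, mkCalls(free[1L], "L1", extraKey, 0.5))
            expect_true(all(got %in% voteClass1Kit(more, roster)))
        }
        ## raising the VAF floor weakly shrinks the output
        strict <- voteClass1Kit(base, roster,
                                consensusConfig(lineVafMin = 0.3))
        expect_true(all(strict %in% got))
    })
})

test_that("cross-kit intersection restricts Class 1 to the CTR", {
    ctr <- RegionSet("c", 0, 100)
    votes <- list(K1 = c("c:10:A:G", "c:20:T:C"),
                  K2 = c("c:10:A:G", "c:30:G:A"),
                  K3 = c("c:10:A:G", "c:20:T:C"))
    cfg <- consensusConfig(replicatedKits = c("K1", "K2", "K3"))
    expect_equal(buildClass1(votes, ctr, cfg), "c:10:A:G")
    ## a variant in all kits but outside the CTR is excluded
    votes2 <- lapply(votes, c, "c:500:A:T")
    expect_equal(buildClass1(votes2, ctr, cfg), "c:10:A:G")
    ## missing kit errors
    expect_error(buildClass1(votes[1:2], ctr, cfg), "K3")
    ## random vote sets equal the brute-force intersection oracle
    withr::with_seed(23, {
        pool <- sprintf("c:%d:A:G", sample(1:400, 120))
        v <- list(K1 = sample(pool, 60), K2 = sample(pool, 60),
                  K3 = sample(pool, 60))
        got <- buildClass1(v, ctr, cfg)
        oracle <- Filter(function(k) {
            all(vapply(v, function(s) k %in% s, logical(1))) &&
                parseVariantKey(k)$pos <= 100
        }, pool)
        expect_setequal(got, unique(oracle))
    })
})

test_that("m-of-n consensus counts distinct caller support", {
    calls <- list(a = c("k1", "k2"), b = c("k1", "k3"), c = "k1",
                  d = c("k2", "k3"), e = character(), f = "k3")
    ## support tallies: k1 = a,b,c = 3; k2 = a,d = 2; k3 = b,d,f = 3
    out2 <- mOfNConsensus(calls, m = 3L)
    expect_setequal(out2$key, c("k1", "k3"))
    expect_equal(out2$support, c(3L, 3L))
    expect_equal(nrow(mOfNConsensus(calls, m = 4L)), 0L)
    expect_error(mOfNConsensus(calls, m = 0L), "m")
    ## randomized support patterns equal the counting oracle
    withr::with_seed(29, {
        keys <- sprintf("c:%d:A:G", 1:500)
        callers <- lapply(1:6, function(i)
            sample(keys, stats::rbinom(1, 500, 0.4)))
        names(callers) <- paste0("caller", 1:6)
        out <- mOfNConsensus(callers, 3L)
        tallies <- vapply(keys, function(k)
            sum(vapply(callers, function(s) k %in% s, logical(1))),
            numeric(1))
        expect_setequal(out$key, keys[tallies >= 3])
    })
})

test_that("Class 2 requires dual WGS and dual WES-kit support on one line", {
    cosmic <- RegionSet("c", 0, 1000, "cosmicHcCoding")
    ctr <- RegionSet("c", 0, 100, "ctr")   # candidate domain is 100..1000
    wgs <- data.table::data.table(
        caller = c("wgsA", "wgsB"), lineId = "TES")
    wgs$key <- "c:500:A:G"
    wes <- data.table::data.table(kitId = c("WES1", "WES2"), lineId = "TES")
    wes$key <- "c:500:A:G"
    expect_equal(buildClass2(wgs, wes, cosmic, ctr), "c:500:A:G")
    ## support split across lines does not qualify
    wesB <- data.table::copy(wes); wesB$lineId <- "LIV"
    expect_length(buildClass2(wgs, wesB, cosmic, ctr), 0)
    ## single WGS caller insufficient
    expect_length(buildClass2(wgs[1L], wes, cosmic, ctr), 0)
    ## inside the CTR is excluded regardless of support
    wgsIn <- data.table::copy(wgs); wgsIn$key <- "c:50:A:G"
    wesIn <- data.table::copy(wes); wesIn$key <- "c:50:A:G"
    expect_length(buildClass2(wgsIn, wesIn, cosmic, ctr), 0)
})

test_that("multi-allelic loci are flagged and excluded from the truth set", {
    perLine <- list(line1 = "chr1:100:A:G", line2 = "chr1:100:A:T",
                    line3 = c("chr1:200:C:T", "chr2:100:G:A"))
    fl <- flagMultiallelic(perLine)
    expect_equal(nrow(fl), 1L)
    expect_equal(fl$pos, 100L)
    expect_equal(fl$alts, "G,T")
    ## same alt in two lines is not flagged
    expect_equal(nrow(flagMultiallelic(list(a = "c:1:A:G", b = "c:1:A:G"))), 0L)
    ## assembly drops both keys at the flagged locus
    ts <- assembleTruthSet(c("chr1:100:A:G", "chr1:200:C:T"),
                           "chr1:100:A:T", fl)
    expect_equal(class1Keys(ts), "chr1:200:C:T")
    expect_length(class2Keys(ts), 0)
    expect_equal(nrow(multiallelicLoci(ts)), 1L)
    ## randomized genotype tables vs a group-by oracle
    withr::with_seed(31, {
        tab <- data.table::data.table(
            line = sample(paste0("L", 1:6), 300, TRUE),
            pos = sample(1:80, 300, TRUE),
            alt = sample(c("A", "C", "G", "T"), 300, TRUE))
        tab$ref <- "N"
        tab <- tab[tab$alt != "N"]
        keys <- paste("c", tab$pos, tab$ref, tab$alt, sep = ":")
        perLine <- split(keys, tab$line)
        fl <- flagMultiallelic(perLine)
        oracle <- tapply(tab$alt, tab$pos, function(a) length(unique(a)))
        expect_setequal(fl$pos, as.integer(names(oracle)[oracle >= 2]))
    })
})

test_that("truth-set invariants hold (disjoint classes, exclusions applied)", {
    expect_error(new("TruthSet", class1 = "c:1:A:G", class2 = "c:1:A:G",
                     multiallelicLoci = flagMultiallelic(list()),
                     meta = data.frame()), "disjoint")
    ts <- assembleTruthSet(c("c:1:A:G"), c("c:1:A:G", "c:2:A:T"))
    expect_equal(class2Keys(ts), "c:2:A:T")  # class2 deduplicated vs class1
})

test_that("pooled confirmation reports detection and VAF agreement", {
    ts <- assembleTruthSet(c("c:1:A:G", "c:2:C:T"), character())
    ev <- data.table::data.table(vaf = c(0.05, 0.10))
    ev$key <- c("c:1:A:G", "c:2:C:T")
    ## consensus superset with counts right at expectation
    pc <- data.table::data.table(dp = c(2000L, 2000L), adp = c(100L, 200L))
    pc$key <- c("c:1:A:G", "c:2:C:T")
    rep1 <- confirmPositives(ts, pc, ev)
    expect_equal(rep1$fractionDetected, 1)
    expect_equal(rep1$fractionConfirmed, 1)
    ## empty consensus confirms nothing
    rep0 <- confirmPositives(ts, pc[0L], ev)
    expect_equal(rep0$fractionDetected, 0)
    expect_equal(rep0$fractionConfirmed, 0)
    expect_setequal(rep0$undetected, class1Keys(ts))
    ## far-off observed VAF is detected but not confirmed
    pcBad <- data.table::data.table(dp = c(2000L, 2000L), adp = c(600L, 200L))
    pcBad$key <- c("c:1:A:G", "c:2:C:T")
    repB <- confirmPositives(ts, pcBad, ev)
    expect_equal(repB$fractionDetected, 1)
    expect_equal(repB$fractionConfirmed, 0.5)
    expect_equal(repB$vafOutliers, "c:1:A:G")
})
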