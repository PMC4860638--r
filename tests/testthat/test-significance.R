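# a NullDistribution built directly, for exact p-value arithmetic
makeNull <- function(clusters, B) {
    new("NullDistribution", B = as.integer(B), clusters = clusters,
        d = 3e5, r = 3e5, seed = 1L, binSize = 100L)
}
oneCluster <- function(score, lengthBp = 1e5, nPatients = 3, sign = 1L) {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, lengthBp))
    gr$score <- score; gr$sign <- sign
    gr$nPatients <- nPatients; gr$lengthBp <- lengthBp
    gr
}

test_that("FDC1 counts per-permutation maxima exceeding the observed score", {
    rc <- data.frame(perm = 1:1000,
                     score = c(rep(5, 950), rep(20, 50)),
                     lengthBp = 1e5, nPatients = 2, sign = 1L)
    null <- makeNull(rc, 1000)
    expect_equal(fdcPvalue(oneCluster(10), null, 1), 0.05)
    expect_equal(fdcPvalue(oneCluster(30), null, 1), 0)     # above all maxima
    expect_equal(fdcPvalue(oneCluster(1), null, 1), 1)      # below all maxima
    # opposite-sign random clusters are never compared
    expect_equal(fdcPvalue(oneCluster(1, sign = -1L), null, 1), 0)
})

test_that("FDC2/3 restrict the competing random clusters", {
    rc <- data.frame(perm = rep(1:10, each = 2),
                     score = rep(c(50, 8), 10),
                     lengthBp = rep(c(5e5, 5e4), 10),
                     nPatients = rep(c(2, 5), 10),
                     sign = 1L)
    null <- makeNull(rc, 10)
    obs <- oneCluster(10, lengthBp = 1e5, nPatients = 4)
    expect_equal(fdcPvalue(obs, null, 1), 1)    # the long 50s dominate
    expect_equal(fdcPvalue(obs, null, 2), 0)    # length filter removes them
    # patient filter: short clusters have 5 patients > observed 4
    expect_equal(fdcPvalue(obs, null, 3), 0)
    obs2 <- oneCluster(6, lengthBp = 1e5, nPatients = 5)
    expect_equal(fdcPvalue(obs2, null, 2), 1)   # the short 8s exceed 6
    expect_equal(fdcPvalue(obs2, null, 3), 1)
})

test_that("FDC4/5 use residual exceedance and need 3 clusters", {
    set.seed(61)
    len <- runif(200, 1e4, 1e6)
    rc <- data.frame(perm = 1:200, score = 2 + 1e-5 * len + rnorm(200),
                     lengthBp = len, nPatients = sample(1:5, 200, TRUE),
                     sign = 1L)
    null <- makeNull(rc, 200)
    big <- fdcPvalue(oneCluster(100, 5e5), null, 4)
    small <- fdcPvalue(oneCluster(0.1, 5e5), null, 4)
    expect_lt(big, 0.02)
    expect_gt(small, 0.5)
    expect_false(is.na(fdcPvalue(oneCluster(5, 5e5), null, 5)))
    tiny <- makeNull(rc[1:2, ], 2)
    expect_warning(p <- fdcPvalue(oneCluster(5), tiny, 4), "fewer than 3")
    expect_true(is.na(p))
})

test_that("permutation conserves each patient's run content per chromosome", {
    set.seed(62)
    lay <- genomeLayout(c(chr1 = 2e5, chr2 = 1e5), binSize = 100)
    v <- numeric(totalBins(lay))
    v[101:150] <- 0.5          # chr1 runs
    v[300:320] <- -0.25
    v[2100:2160] <- 1          # chr2 run
    sig <- makeHFSignal(v, lay)
    runSignature <- function(s) {
        runs <- focalWave:::nonzeroRuns(s)
        lens <- runs$end - runs$start + 1
        sums <- vapply(seq_len(nrow(runs)), function(i)
            sum(s@values[runs$start[i]:runs$end[i]]), numeric(1))
        lapply(split(data.frame(lens, sums), runs$chrom), function(d)
            d[order(d$lens, d$sums), ])
    }
    ref <- runSignature(sig)
    for (i in 1:100) {
        p <- permuteSignal(sig)
        got <- runSignature(p)
        expect_equal(got, ref, ignore_attr = TRUE)
    }
    # no nonzero runs: output all zero
    empty <- permuteSignal(makeHFSignal(numeric(50)))
    expect_true(all(empty@values == 0))
    # a run occupying an entire chromosome has only one placement
    full <- makeHFSignal(c(rep(1, 2000), numeric(1000)),
                         genomeLayout(c(chr1 = 2e5, chr2 = 1e5),
                                      binSize = 100))
    expect_equal(permuteSignal(full)@values, full@values)
})

test_that("the null is a pure function of its seed", {
    set.seed(63)
    sim <- simulateCohort(smallCohortSpec(63))
    tracks <- lapply(sim$patients, function(p)
        computeLog2Ratio(p$tumor, p$normal))
    signals <- lapply(tracks, computeSampleSignal,
                      params = waveletParams(nLevels = 12))
    n1 <- buildNull(signals, B = 25L, seed = 99L)
    n2 <- buildNull(signals, B = 25L, seed = 99L)
    expect_identical(n1@clusters, n2@clusters)
    n3 <- buildNull(signals, B = 25L, seed = 100L)
    expect_false(identical(n1@clusters, n3@clusters))
    expect_equal(max(n1@clusters$perm), 25)
    expect_true(all(abs(n1@clusters$score) > 0))
})

test_that("all-zero cohorts yield an empty null", {
    sigs <- list(makeHFSignal(numeric(100)), makeHFSignal(numeric(100)))
    null <- buildNull(sigs, B = 5L, seed = 1L)
    expect_equal(nrow(null@clusters), 0)
})

test_that("significance filtering respects alpha and ordering", {
    rc <- data.frame(perm = 1:100, score = runif(100, 0, 10),
                     lengthBp = 1e5, nPatients = 2, sign = 1L)
    null <- makeNull(rc, 100)
    cl <- c(oneCluster(50), oneCluster(2), oneCluster(30))
    expect_equal(length(significantClusters(cl, null, 1, alpha = 0)),
                 sum(fdcPvalue(cl, null, 1) == 0))
    all3 <- significantClusters(cl, null, 1, alpha = 1)
    expect_equal(length(all3), 3)
    expect_equal(all3$score, c(50, 30, 2))  # |score| descending
})
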