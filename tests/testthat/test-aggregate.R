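test_that("summation is exact, order-invariant, and tracks support", {
    lay <- oneChromLayout(6)
    a <- makeHFSignal(c(0, 1, 1, -1, 0, 2), lay)
    b <- makeHFSignal(c(0, 1, 0, 0, 0, -1), lay)
    one <- sumSamples(list(a))
    expect_equal(one@values, a@values)
    two <- sumSamples(list(a, a))
    expect_equal(two@values, 2 * a@values)
    expect_equal(two@support, c(0L, 2L, 2L, 2L, 0L, 2L))
    ab <- sumSamples(list(a, b))
    ba <- sumSamples(list(b, a))
    expect_equal(ab@values, ba@values)
    expect_equal(ab@support, ba@support)
    expect_error(sumSamples(list(a, makeHFSignal(rnorm(5)))),
                 "same layout")
})

test_that("run extraction splits at sign changes and zeros", {
    s <- makeSumSignal(c(0, 1, 1, -1, 0, 2))
    runs <- extractRuns(s)
    expect_equal(runs$start, c(2L, 4L, 6L))
    expect_equal(runs$end, c(3L, 4L, 6L))
    expect_equal(runs$sign, c(1L, -1L, 1L))
    expect_equal(runs$score, c(2, -1, 2))
    expect_equal(nrow(extractRuns(makeSumSignal(numeric(8)))), 0)
    expect_equal(countSignSegments(c(0, 1, 1, -1, 0, 2)), 3)
    expect_equal(countSignSegments(numeric(10)), 0)
    expect_equal(countSignSegments(c(1, 1, 0, -2)) +
                 countSignSegments(c(3, 0, -1)),
                 countSignSegments(c(1, 1, 0, -2, 0, 3, 0, -1)))
})

test_that("grouping emits the max-|score| subgroup per group", {
    # a single isolated run is its own cluster
    s <- makeSumSignal(c(rep(0, 10), rep(2, 5), rep(0, 10)))
    cl <- groupAndCluster(s, d = 300, r = 300)
    expect_equal(length(cl), 1)
    expect_equal(cl$score, 10)
    expect_equal(BiocGenerics::start(cl), 1001)
    expect_equal(BiocGenerics::end(cl), 1500)

    # two same-sign runs separated by more than d: two clusters
    v <- c(rep(1, 3), rep(0, 10), rep(1, 3))
    cl2 <- groupAndCluster(makeSumSignal(v), d = 500, r = 500)
    expect_equal(length(cl2), 2)
    # within d: one group; with r = d both runs share the subgroup
    cl3 <- groupAndCluster(makeSumSignal(v), d = 1200, r = 1200)
    expect_equal(length(cl3), 1)
    expect_equal(cl3$score, 6)
    # r < gap < d: two subgroups, the (leftmost) max-|score| one wins
    v2 <- c(rep(2, 3), rep(0, 10), rep(1, 3))
    cl4 <- groupAndCluster(makeSumSignal(v2), d = 1200, r = 500)
    expect_equal(length(cl4), 1)
    expect_equal(cl4$score, 6)
    expect_equal(BiocGenerics::end(cl4), 300)
})

test_that("d = r = 0 degenerates to one cluster per run", {
    set.seed(51)
    v <- numeric(400)
    v[sample(400, 40)] <- rnorm(40)
    s <- makeSumSignal(v)
    runs <- extractRuns(s)
    cl <- groupAndCluster(s, d = 0, r = 0)
    expect_equal(length(cl), nrow(runs))
    expect_equal(sort(cl$score), sort(runs$score))
})

test_that("grouping matches the brute-force oracle on random instances", {
    set.seed(52)
    for (i in 1:40) {
        runs <- randomRuns(sample(2:30, 1))
        dB <- sample(0:120, 1); rB <- sample(0:120, 1)
        mine <- focalWave:::clusterRuns(runs, dB, rB)
        mine <- mine[order(mine$chrom, mine$sign, mine$start), ]
        oracle <- bruteClusterOracle(runs, dB, rB)
        rownames(mine) <- rownames(oracle) <- NULL
        expect_equal(mine[, names(oracle)], oracle)
    }
})

test_that("compiled and reference clustering agree", {
    set.seed(53)
    for (i in 1:25) {
        runs <- randomRuns(sample(2:60, 1))
        dB <- sample(0:100, 1); rB <- sample(0:100, 1)
        a <- focalWave:::clusterRuns(runs, dB, rB)
        b <- focalWave:::cpp_cluster_runs(
            runs$start, runs$end, runs$sign, runs$chrom, runs$score,
            runs$support, dB, rB)
        a <- a[order(a$chrom, a$sign, a$start), ]
        b <- b[order(b$chrom, b$sign, b$start), ]
        rownames(a) <- rownames(b) <- NULL
        expect_equal(a, b[, names(a)])
    }
})

test_that("more permissive distances never create more groups", {
    set.seed(54)
    runs <- randomRuns(40)
    nClusters <- function(d, r)
        nrow(focalWave:::clusterRuns(runs, d, r))
    for (d in c(0, 10, 50, 200, 1000))
        expect_gte(nClusters(d, d), nClusters(d * 2 + 10, d * 2 + 10))
})

test_that("clusters report scores recomputable from the sum signal", {
    set.seed(55)
    v <- numeric(2000)
    v[300:380] <- 1.5
    v[420:450] <- 2.0
    v[1500:1540] <- -1.0
    s <- makeSumSignal(v)
    cl <- groupAndCluster(s, d = 1e4, r = 1e4)
    for (i in seq_along(cl)) {
        b1 <- genomeToBin(s@layout, "chr1", BiocGenerics::start(cl)[i])
        b2 <- genomeToBin(s@layout, "chr1", BiocGenerics::end(cl)[i])
        inRange <- v[b1:b2]
        expect_equal(cl$score[i],
                     sum(inRange[sign(inRange) == cl$sign[i]]))
    }
    # disjoint and |score|-sorted
    expect_false(is.unsorted(rev(abs(cl$score))))
})

test_that("gene annotation uses >= 1 bp overlap discipline", {
    cl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000))
    cl$score <- 5
    genes <- GenomicRanges::GRanges(
        c("chr1", "chr1", "chr1"),
        IRanges::IRanges(c(1000, 500, 2500), c(2000, 999, 3000)))
    genes$name <- c("inside", "adjacent", "far")
    ann <- annotateClusters(cl, genes)
    expect_equal(ann$genes, "inside")   # adjacent (end = start - 1) excluded
    none <- suppressWarnings(annotateClusters(
        GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 10),
                               score = 1), genes))
    expect_equal(none$genes, "")
    bedPath <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t999\t2000\tinside", "chr1\t499\t999\tadjacent"),
               bedPath)
    expect_equal(annotateClusters(cl, bedPath)$genes, "inside")
    bad <- tempfile(fileext = ".bed")
    writeLines("chr1\tnot-a-number\tx", bad)
    expect_error(annotateClusters(cl, bad), "malformed BED")
})
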