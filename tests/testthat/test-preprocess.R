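test_that("layout bins tile chromosomes and the index map round-trips", {
    lay <- genomeLayout(c(chr1 = 1050, chr2 = 400), binSize = 100)
    expect_equal(unname(binsPerChrom(lay)), c(11, 4))  # partial bin kept
    expect_equal(totalBins(lay), 15)
    g <- binToGenome(lay, 11)
    expect_equal(g$start, 1001)
    expect_equal(g$end, 1050)                          # clipped to length
    idx <- seq_len(totalBins(lay))
    g <- binToGenome(lay, idx)
    expect_equal(genomeToBin(lay, g$chrom, g$start), idx)
    expect_equal(genomeToBin(lay, g$chrom, g$end), idx)

    # a 3.2 Gbp genome at 100 bp bins
    big <- genomeLayout(setNames(rep(1e8, 32), paste0("chr", 1:32)))
    expect_equal(totalBins(big), 32e6)
})

test_that("read counting tallies leftmost mapped bases from a BAM", {
    skip_if_not_installed("Rsamtools")
    lay <- genomeLayout(c(chrA = 50, chrB = 30), binSize = 10)
    # build a SAM fixture in code, convert to BAM
    set.seed(31)
    pos <- c(sample(1:41, 100, replace = TRUE), 5, 5)
    chrom <- c(sample(c("chrA", "chrB"), 100, replace = TRUE,
                      prob = c(.7, .3)), "chrA", "chrA")
    pos[chrom == "chrB"] <- pmin(pos[chrom == "chrB"], 21)
    flags <- rep(0L, 102)
    flags[1] <- 1024L  # one duplicate, must be skipped
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6\tSO:coordinate",
        "@SQ\tSN:chrA\tLN:50",
        "@SQ\tSN:chrB\tLN:30",
        {
            o <- order(match(chrom, c("chrA", "chrB")), pos)
            sprintf("r%03d\t%d\t%s\t%d\t60\t10M\t*\t0\t0\t%s\t*",
                    seq_along(pos), flags[o], chrom[o], pos[o],
                    strrep("A", 10))
        }), sam)
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
    counts <- countReadsPerBase(bam, lay)
    # brute-force histogram of kept read starts
    keep <- flags == 0L
    expect_equal(counts$chrA,
                 as.numeric(tabulate(pos[keep & chrom == "chrA"], 50)))
    expect_equal(counts$chrB,
                 as.numeric(tabulate(pos[keep & chrom == "chrB"], 30)))
    expect_gte(counts$chrA[5], 2)  # the two planted reads at position 5
})

test_that("winsorization caps spikes at the window quantile", {
    expect_equal(removeOutliers(rep(3, 500)), rep(3, 500))  # constant
    expect_equal(removeOutliers(numeric(400)), numeric(400))

    x <- rep(1, 601)
    x[300] <- 1000
    capped <- removeOutliers(x)
    expect_equal(capped[300], 1)          # 0.95-quantile of an all-1 window
    expect_equal(capped[-300], x[-300])

    set.seed(32)
    y <- as.numeric(rnbinom(800, size = 5, mu = 20))
    # one capping pass against the brute-force window-quantile oracle
    expect_equal(removeOutliers(y, maxIter = 1), winsorizeOracle(y))
    expect_true(all(removeOutliers(y) <= y))  # no count increases

    expect_warning(removeOutliers(rep(1, 50), window = 200), "window")
})

test_that("winsorization is idempotent on realistic coverage tracks", {
    set.seed(33)
    y <- as.numeric(rnbinom(2000, size = 20, mu = 40))
    y[sample(2000, 5)] <- 5000          # isolated spikes
    once <- removeOutliers(y)
    expect_equal(removeOutliers(once), once)
})

test_that("binning sums constituent bases and conserves mass", {
    lay <- genomeLayout(c(chr1 = 4), binSize = 2)
    bc <- binCounts(list(chr1 = c(1, 1, 2, 0)), lay)
    expect_equal(counts(bc), c(2, 2))

    lay2 <- genomeLayout(c(chr1 = 250, chr2 = 100), binSize = 100)
    pb <- list(chr1 = as.numeric(rpois(250, 3)),
               chr2 = as.numeric(rpois(100, 3)))
    bc2 <- binCounts(pb, lay2)
    expect_equal(length(counts(bc2)), 4)   # trailing 50 bp partial bin
    expect_equal(unname(perChromosomeTotals(bc2)),
                 c(sum(pb$chr1), sum(pb$chr2)))  # exact mass conservation
    expect_error(binCounts(list(chr1 = 1:10), lay2), "match the layout")
})

test_that("log2 ratio is chromosome-normalized with invalid-bin contract", {
    lay <- genomeLayout(c(chr1 = 400), binSize = 100)
    tum <- binnedCoverage(c(20, 40, 10, 30), lay, role = "tumor")
    nrm <- binnedCoverage(c(10, 20, 5, 15), lay, role = "normal")
    tr <- computeLog2Ratio(tum, nrm)
    expect_equal(log2Ratio(tr), rep(0, 4))  # equal normalized depth

    tum2 <- binnedCoverage(c(40, 40, 20, 0), lay, role = "tumor")
    nrm2 <- binnedCoverage(c(10, 20, 0, 15), lay, role = "normal")
    tr2 <- computeLog2Ratio(tum2, nrm2)
    expect_false(validBins(tr2)[3])  # Normal_i = 0
    expect_false(validBins(tr2)[4])  # Tumor_i = 0
    expect_equal(log2Ratio(tr2)[1],
                 log2((40 / 100) / (10 / 45)))

    # tumor depth exactly double the normal, uniformly scaled library
    tum3 <- binnedCoverage(c(40, 80), genomeLayout(c(chr1 = 200)),
                           role = "tumor")
    nrm3 <- binnedCoverage(c(20, 20), genomeLayout(c(chr1 = 200)),
                           role = "normal")
    r3 <- log2Ratio(computeLog2Ratio(tum3, nrm3))
    expect_equal(r3[2] - r3[1], 1)  # bin2 is doubled relative to bin1
})

test_that("ratio is antisymmetric and library-scale invariant", {
    set.seed(34)
    lay <- genomeLayout(c(chr1 = 5e4, chr2 = 3e4), binSize = 100)
    tc <- as.numeric(rnbinom(totalBins(lay), size = 10, mu = 30))
    nc <- as.numeric(rnbinom(totalBins(lay), size = 10, mu = 25))
    tum <- binnedCoverage(tc, lay, role = "tumor")
    nrm <- binnedCoverage(nc, lay, role = "normal")
    a <- computeLog2Ratio(tum, nrm)
    b <- computeLog2Ratio(binnedCoverage(nc, lay, role = "tumor"),
                          binnedCoverage(tc, lay, role = "normal"))
    both <- validBins(a) & validBins(b)
    expect_equal(log2Ratio(a)[both], -log2Ratio(b)[both])

    k <- 7
    scaled <- computeLog2Ratio(binnedCoverage(k * tc, lay, role = "tumor"),
                               nrm)
    expect_equal(log2Ratio(scaled), log2Ratio(a))

    zero <- binnedCoverage(c(rep(0, 500), nc[-(1:500)]), lay,
                           role = "normal")
    expect_warning(computeLog2Ratio(tum, zero), "zero total")
})
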