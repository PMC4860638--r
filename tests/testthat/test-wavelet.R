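test_that("symmetric extension mirrors and round-trips", {
    expect_equal(symmetricExtend(c(1, 2, 3), 8),
                 c(1, 2, 3, 3, 2, 1, 1, 2))
    x <- rnorm(16)
    expect_identical(symmetricExtend(x), x)  # power of two: unchanged
    y <- rnorm(300)
    ext <- symmetricExtend(y)
    expect_equal(length(ext), 512)
    expect_identical(ext[seq_along(y)], y)   # extract-after-extend
    expect_error(symmetricExtend(y, 600), "power of two")
    expect_error(symmetricExtend(y, 128), ">=")
})

test_that("Haar SWT follows the average/half-difference recursion", {
    co <- haarSWT(rep(5, 4), 2)
    expect_true(all(vapply(co$detail, function(w) all(w == 0), logical(1))))
    expect_equal(co$scaling, rep(5, 4))

    co <- haarSWT(c(0, 0, 1, 1), 1)
    expect_equal(co$detail[[1]], c(0, -1/2, 0, 1/2))

    expect_error(haarSWT(rnorm(8), 4), "too many levels")
    expect_error(haarSWT(rnorm(5), 1), "power of two")
})

test_that("unthresholded analysis + synthesis is perfect reconstruction", {
    set.seed(11)
    for (J in c(4, 7, 10)) {
        x <- rnorm(2^J)
        co <- haarSWT(x, J - 1)
        expect_lt(max(abs(inverseHaarSWT(co) - x)), 1e-10)
    }
})

test_that("high/low-frequency parts partition the signal", {
    set.seed(12)
    x <- rnorm(256)
    co <- haarSWT(x, 5)
    yh <- reconstructYHigh(co)
    lo <- co
    lo$detail <- lapply(lo$detail, function(w) w * 0)
    expect_lt(max(abs(yh + inverseHaarSWT(lo) - x)), 1e-10)
})

test_that("level threshold is the MAD-based universal threshold", {
    expect_equal(levelThreshold(numeric(32), 2), 0)
    w <- c(-1, 0.5, 2, -0.25)
    expect_equal(levelThreshold(w, 2), 2 * levelThreshold(w, 1))
    set.seed(13)
    z <- rnorm(1e5)
    lam <- levelThreshold(z, 1)
    expect_equal(lam, sqrt(2 * log(1e5)), tolerance = 0.02)
})

test_that("hard thresholding zeroes |w| <= lambda, non-strictly", {
    expect_equal(hardThreshold(c(-3, 0.5, 2), 1), c(-3, 0, 2))
    expect_equal(hardThreshold(c(-3, 0, 2), 0), c(-3, 0, 2))
    expect_equal(hardThreshold(c(-3, 0.5, 2), Inf), c(0, 0, 0))
    expect_equal(hardThreshold(c(-1, 1, 2), 1), c(0, 0, 2))  # non-strict
})

test_that("y_HIGH is zero for constant input and dipolar at a step", {
    co <- haarSWT(rep(2.5, 64), 4)
    expect_true(all(reconstructYHigh(co) == 0))

    x <- c(rep(0, 128), rep(1, 128))
    co <- haarSWT(symmetricExtend(x), 5)
    yh <- reconstructYHigh(co, length(x))
    # paired opposite-sign lobes flanking the up-step
    expect_gt(yh[129], 0)
    expect_lt(yh[128], 0)
})

test_that("sign filter removes whole disagreeing regions", {
    # scalar (length-one region) cases
    expect_equal(signFilter(0.4, -0.3), 0)
    expect_equal(signFilter(0.4, 0.3), 0.4)
    expect_equal(signFilter(0, 5), 0)
    # a whole region is kept or dropped by the sign of its summed ratio
    yh <- c(0.5, 0.5, 0.5, -0.2, -0.2, 0, 0.3)
    ratio <- c(1, -0.1, 1, 1, 1, 1, -2)  # regions: +(sum>0), -(sum>0), +(-)
    expect_equal(signFilter(yh, ratio),
                 c(0.5, 0.5, 0.5, 0, 0, 0, 0))
})

test_that("both engines produce the same sample signal", {
    set.seed(21)
    spec <- simulationSpec(c(chr1 = 1e6, chr2 = 5e5), nPatients = 1,
                           events = data.frame(
                               chrom = "chr1", start = 2e5 + 1, end = 4e5,
                               dLog2 = 1, kind = "focal",
                               carriers = I(list(1L))),
                           seed = 21)
    sim <- simulateCohort(spec)
    tr <- computeLog2Ratio(sim$patients[[1]]$tumor, sim$patients[[1]]$normal)
    p <- waveletParams(nLevels = 10)
    s1 <- computeSampleSignal(tr, params = p, engine = "cpp")
    s2 <- computeSampleSignal(tr, params = p, engine = "r")
    expect_lt(max(abs(s1@values - s2@values)), 1e-10)
    expect_gt(sum(s1@values != 0), 0)
})

test_that("SWT is shift-covariant (circular)", {
    set.seed(22)
    x <- rnorm(256) + rep(c(0, 2), each = 128)
    k <- 37
    xs <- c(x[(k + 1):256], x[1:k])
    yh <- function(v) {
        co <- haarSWT(v, 5)
        co$detail <- lapply(co$detail, function(w)
            hardThreshold(w, levelThreshold(w, 1)))
        reconstructYHigh(co)
    }
    a <- yh(x); b <- yh(xs)
    expect_equal(b, c(a[(k + 1):256], a[1:k]), tolerance = 1e-10)
})

test_that("thresholded signal is empty under pure Gaussian noise", {
    set.seed(23)
    frac <- replicate(10, {
        x <- rnorm(2^12)
        co <- haarSWT(x, 8)
        co$detail <- lapply(co$detail, function(w)
            hardThreshold(w, levelThreshold(w, 2)))
        yh <- reconstructYHigh(co)
        mean(signFilter(yh, x) != 0)
    })
    expect_lt(mean(frac), 0.01)
})

test_that("parameter arithmetic links J, M and the neighbor scale", {
    p <- waveletParams(J = 25, M = 10)
    expect_equal(p@nLevels, 15L)
    expect_error(waveletParams(J = 10, M = 12), "J must exceed M")
    expect_error(waveletParams(J = 20, M = 10, nLevels = 5),
                 "inconsistent")
    # resolution guard: depth must fit the extended signal
    expect_error(computeSampleSignal(
        new("CopyRatioTrack", sampleId = "s", log2Ratio = rnorm(64),
            valid = rep(TRUE, 64), layout = oneChromLayout(64)),
        params = waveletParams(nLevels = 15)), "too large")
})
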