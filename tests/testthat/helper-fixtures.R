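# shared fixtures and independent oracles

# a one-chromosome layout covering n bins
oneChromLayout <- function(n, binSize = 100L)
    genomeLayout(c(chr1 = n * binSize), binSize = binSize)

# wrap a plain numeric vector as a SumSignal on a fresh layout
makeSumSignal <- function(values, support = NULL, nSamples = NULL,
                          binSize = 100L) {
    n <- length(values)
    if (is.null(support)) support <- as.integer(values != 0)
    if (is.null(nSamples)) nSamples <- max(1L, max(support))
    new("SumSignal", values = as.numeric(values),
        support = as.integer(support), nSamples = as.integer(nSamples),
        origin = seq_len(n), junctions = integer(0),
        layout = oneChromLayout(n, binSize))
}

# wrap a numeric vector as a HighFreqSignal (identity ratio)
makeHFSignal <- function(values, layout = oneChromLayout(length(values)),
                         sampleId = "s1") {
    new("HighFreqSignal", sampleId = sampleId,
        values = as.numeric(values), yHigh = as.numeric(values),
        ratio = as.numeric(values), origin = seq_along(values),
        junctions = integer(0), layout = layout,
        params = waveletParams())
}

# independent brute-force grouping oracle: groups and subgroups as
# connected components of the "gap <= threshold" relation among
# same-sign, same-chromosome runs, winner = max |score| (leftmost tie)
bruteClusterOracle <- function(runs, dBins, rBins) {
    components <- function(idx, thr) {
        k <- length(idx)
        adj <- matrix(FALSE, k, k)
        for (a in seq_len(k)) for (b in seq_len(k)) {
            if (a == b) { adj[a, b] <- TRUE; next }
            i <- idx[a]; j <- idx[b]
            gap <- max(runs$start[j] - runs$end[i] - 1,
                       runs$start[i] - runs$end[j] - 1)
            adj[a, b] <- gap <= thr
        }
        # transitive closure
        repeat {
            nxt <- adj | (adj %*% adj > 0)
            if (identical(nxt, adj)) break
            adj <- nxt
        }
        comp <- rep(NA_integer_, k)
        cid <- 0L
        for (a in seq_len(k)) if (is.na(comp[a])) {
            cid <- cid + 1L
            comp[adj[a, ]] <- cid
        }
        comp
    }
    out <- list()
    for (key in split(seq_len(nrow(runs)),
                      list(runs$chrom, runs$sign), drop = TRUE)) {
        grp <- components(key, dBins)
        for (gids in split(key, grp)) {
            sub <- components(gids, rBins)
            scores <- vapply(split(gids, sub),
                             function(ii) sum(runs$score[ii]), numeric(1))
            starts <- vapply(split(gids, sub),
                             function(ii) min(runs$start[ii]), numeric(1))
            best <- which(abs(scores) == max(abs(scores)))
            best <- best[which.min(starts[best])]
            ii <- split(gids, sub)[[best]]
            out[[length(out) + 1L]] <- data.frame(
                start = min(runs$start[ii]), end = max(runs$end[ii]),
                sign = runs$sign[ii[1]], chrom = runs$chrom[ii[1]],
                score = scores[[best]], support = max(runs$support[ii]),
                nRuns = length(ii))
        }
    }
    res <- do.call(rbind, out)
    res[order(res$chrom, res$sign, res$start), , drop = FALSE]
}

# random non-overlapping run table for oracle comparisons
randomRuns <- function(nRuns, nChrom = 2, span = 2000) {
    chrom <- sort(sample.int(nChrom, nRuns, replace = TRUE))
    runs <- do.call(rbind, lapply(split(seq_len(nRuns), chrom), function(ii) {
        k <- length(ii)
        bounds <- sort(sample.int(span, 2 * k))
        data.frame(start = bounds[seq(1, 2 * k, 2)],
                   end = bounds[seq(2, 2 * k, 2)],
                   sign = sample(c(-1L, 1L), k, replace = TRUE),
                   chrom = chrom[ii])
    }))
    runs$score <- runs$sign * stats::runif(nRuns, 0.1, 10)
    runs$support <- sample.int(5, nRuns, replace = TRUE)
    rownames(runs) <- NULL
    runs
}

# brute-force sliding-window winsorization oracle (type-1 quantile of the
# centered window, values above capped)
winsorizeOracle <- function(x, window = 200L, q = 0.95) {
    n <- length(x)
    out <- x
    left <- window %/% 2 - 1
    right <- window - window %/% 2
    for (i in seq_len(n)) {
        w <- x[max(1, i - left):min(n, i + right)]
        thr <- sort(w)[ceiling(q * length(w))]
        if (x[i] > thr) out[i] <- thr
    }
    out
}

# small cohort spec used by several significance tests: two focal events
# on different chromosomes with partially overlapping carrier sets
smallCohortSpec <- function(seed, nPatients = 5L) {
    events <- data.frame(chrom = c("chr1", "chr2"),
                         start = c(2e6 + 1, 1e6 + 1),
                         end = c(2.5e6, 1.4e6),
                         dLog2 = c(0.8, -0.8),
                         kind = c("focal", "focal"))
    events$carriers <- list(1:3, c(2L, 4L))
    simulationSpec(c(chr1 = 5e6, chr2 = 5e6), nPatients = nPatients,
                   events = events, seed = seed)
}

runSmallPipeline <- function(seed, B = 200L, ...) {
    sim <- simulateCohort(smallCohortSpec(seed))
    runCohortPipeline(sim$patients, sim$layout, B = B, seed = seed,
                      maskLowMapping = FALSE, ...)
}
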