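# maximal nonzero runs of one patient's signal (sign may vary inside,
# runs split at chromosome boundaries); values kept intact and in order
nonzeroRuns <- function(signal) {
    ch <- chromOfBin(signal@layout, signal@origin)
    cpp_nonzero_runs(signal@values, ch)
}

# flatten a patient's runs for the C++ placement kernels
flattenRuns <- function(signal, runs) {
    lens <- runs$end - runs$start + 1L
    idx <- sequence(lens, from = runs$start)
    list(len = as.integer(lens),
         off = as.integer(cumsum(c(1L, lens[-length(lens)]))),
         val = signal@values[idx])
}

# concatenated-coordinate territory [lo, hi] of each chromosome
chromTerritories <- function(signal) {
    ch <- chromOfBin(signal@layout, signal@origin)
    nChrom <- length(chromLengths(signal@layout))
    lo <- integer(nChrom); hi <- integer(nChrom)
    for (c in seq_len(nChrom)) {
        w <- which(ch == c)
        if (length(w)) { lo[c] <- w[1]; hi[c] <- w[length(w)] }
    }
    list(lo = lo, hi = hi)
}

#' Randomly reallocate one patient's altered runs
#'
#' Each maximal nonzero run (values kept intact, in order) is placed at a
#' uniformly random start within the same chromosome's unmasked
#' territory; placements overlapping already-placed runs of the same
#' patient are rejected and redrawn (after `maxTries` rejections the
#' chromosome falls back to sequential random non-overlapping placement,
#' with a warning).  All other positions are zero.  This realizes the
#' null hypothesis that genomic regions in patients are independently
#' altered.
#'
#' @param signal a [HighFreqSignal-class].
#' @param maxTries rejection rounds before the fallback (default 1000).
#' @return A [HighFreqSignal-class] with permuted values.
#' @export
permuteSignal <- function(signal, maxTries = 1000L) {
    runs <- nonzeroRuns(signal)
    out <- signal
    if (nrow(runs) == 0L) {
        out@values <- numeric(length(signal@values))
        return(out)
    }
    terr <- chromTerritories(signal)
    fl <- flattenRuns(signal, runs)
    ps <- cpp_permute_sum(length(signal@values), fl$len,
                          rep(1L, nrow(runs)), as.integer(runs$chrom),
                          fl$off, fl$val,
                          as.integer(terr$lo), as.integer(terr$hi),
                          as.integer(maxTries))
    out@values <- ps$sum
    out
}

#' Build the permutation null distribution
#'
#' For each of `B` permutations, every patient's nonzero runs are
#' independently reallocated within their chromosomes, the permuted
#' signals are summed, and the same run-extraction / grouping /
#' clustering as the observed analysis (with identical `d`, `r`) yields
#' that permutation's random clusters.  The whole null is a pure function
#' of `(signals, d, r, B, seed)`.
#'
#' @param signals list of [HighFreqSignal-class], one per patient.
#' @param d,r grouping distances in bp (must match the observed call).
#' @param B number of permutations (default 1000).
#' @param seed integer RNG seed.
#' @param maxTries rejection rounds per run before fallback placement.
#' @return A [NullDistribution-class].
#' @export
buildNull <- function(signals, d = 3e5, r = 3e5, B = 1000L, seed = 1L,
                      maxTries = 1000L) {
    stopifnot(length(signals) >= 1)
    sig1 <- signals[[1]]
    bs <- binSize(sig1@layout)
    n <- length(sig1@values)
    terr <- chromTerritories(sig1)
    ch <- chromOfBin(sig1@layout, sig1@origin)

    # flatten every patient's runs once, ordered by (patient, chromosome)
    parts <- lapply(seq_along(signals), function(p) {
        runs <- nonzeroRuns(signals[[p]])
        if (nrow(runs) == 0L) return(NULL)
        fl <- flattenRuns(signals[[p]], runs)
        list(len = fl$len, chr = as.integer(runs$chrom), val = fl$val,
             pat = rep(p, nrow(runs)))
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    dBins <- as.integer(floor(d / bs)); rBins <- as.integer(floor(r / bs))
    set.seed(seed)
    if (length(parts) == 0L) {
        clusters <- data.frame(perm = integer(), score = numeric(),
                               lengthBp = numeric(), nPatients = integer(),
                               sign = integer())
    } else {
        allLen <- unlist(lapply(parts, `[[`, "len"))
        allVal <- unlist(lapply(parts, `[[`, "val"))
        allOff <- as.integer(cumsum(c(1L, allLen[-length(allLen)])))
        allPat <- unlist(lapply(parts, `[[`, "pat"))
        allChr <- unlist(lapply(parts, `[[`, "chr"))
        raw <- cpp_build_null(as.integer(B), n, allLen, allPat, allChr,
                              allOff, allVal, as.integer(terr$lo),
                              as.integer(terr$hi), ch, dBins, rBins,
                              as.integer(maxTries))
        clusters <- data.frame(perm = raw$perm, score = raw$score,
                               lengthBp = (raw$end - raw$start + 1) * bs,
                               nPatients = raw$support, sign = raw$sign)
    }
    new("NullDistribution", B = as.integer(B), clusters = clusters,
        d = d, r = r, seed = as.integer(seed), binSize = as.integer(bs))
}

setMethod("show", "NullDistribution", function(object) {
    cat("NullDistribution: B =", object@B, "permutations,",
        nrow(object@clusters), "random clusters (seed", object@seed, ")\n")
})

#' Permutation p-values under the five FDC schemes
#'
#' An observed cluster is compared only against random clusters of the
#' same sign, on absolute score:
#' \describe{
#'   \item{FDC1}{fraction of permutations whose maximum random |score|
#'     reaches the observed |score|.}
#'   \item{FDC2}{as FDC1, restricting each permutation's maximum to
#'     random clusters no longer than the observed cluster.}
#'   \item{FDC3}{as FDC2, additionally requiring the random cluster's
#'     patient count not to exceed the observed one.}
#'   \item{FDC4}{|score| is regressed on length over all pooled same-sign
#'     random clusters; the p-value is the fraction of random clusters
#'     whose regression residual reaches the observed residual.}
#'   \item{FDC5}{as FDC4 with patient count as a second covariate.}
#' }
#' In FDC2/3, permutations with no qualifying random cluster count as
#' non-exceedances.  FDC4/5 need at least 3 pooled random clusters;
#' otherwise the p-value is `NA` with a warning.  The restrictions are
#' nested, so `p_FDC3 <= p_FDC2 <= p_FDC1` always.
#'
#' @param clusters `GRanges` from [groupAndCluster()] (needs `score`,
#'   `sign`, `nPatients`, `lengthBp`).
#' @param null a [NullDistribution-class] built with the same `d`, `r`.
#' @param mode integer 1..5.
#' @return numeric p-values, one per cluster.
#' @export
fdcPvalue <- function(clusters, null, mode = 1L) {
    stopifnot(mode %in% 1:5)
    rc <- null@clusters
    B <- null@B
    obsScore <- abs(clusters$score)
    obsLen <- clusters$lengthBp
    obsPat <- clusters$nPatients
    obsSign <- clusters$sign
    vapply(seq_along(clusters), function(i) {
        same <- rc[rc$sign == obsSign[i], , drop = FALSE]
        if (mode %in% 1:3) {
            if (mode >= 2) same <- same[same$lengthBp <= obsLen[i], ,
                                        drop = FALSE]
            if (mode == 3) same <- same[same$nPatients <= obsPat[i], ,
                                        drop = FALSE]
            if (nrow(same) == 0L) return(0)
            mx <- tapply(abs(same$score), same$perm, max)
            sum(mx >= obsScore[i]) / B
        } else {
            if (nrow(same) < 3L) {
                warning("fewer than 3 random clusters; FDC", mode,
                        " p-value undefined")
                return(NA_real_)
            }
            fit <- if (mode == 4)
                stats::lm(abs(score) ~ lengthBp, data = same)
            else
                stats::lm(abs(score) ~ lengthBp + nPatients, data = same)
            newd <- data.frame(lengthBp = obsLen[i], nPatients = obsPat[i])
            eObs <- obsScore[i] - stats::predict(fit, newdata = newd)
            mean(stats::residuals(fit) >= eObs)
        }
    }, numeric(1))
}

#' Filter clusters by significance
#'
#' @param clusters `GRanges` with p-value columns (see
#'   [runCohortPipeline()]) or to be computed against `null`.
#' @param null a [NullDistribution-class].
#' @param mode FDC scheme 1..5.
#' @param alpha significance level (default 0.1).
#' @return The significant clusters, ordered by `|score|` descending,
#'   with the chosen p-values in a `p` column.
#' @export
significantClusters <- function(clusters, null, mode = 1L, alpha = 0.1) {
    p <- fdcPvalue(clusters, null, mode)
    keep <- !is.na(p) & p <= alpha
    out <- clusters[keep]
    out$p <- p[keep]
    out[order(-abs(out$score))]
}
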