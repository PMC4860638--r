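#' Sum per-patient high-frequency signals into the recurrence signal
#'
#' Element-wise sum of the sign-filtered signals over the common unmasked
#' bin set, plus the per-position count of patients contributing a
#' nonzero value.  All signals must share the same layout and mask.
#'
#' @param signals list of [HighFreqSignal-class] objects.
#' @return A [SumSignal-class].
#' @export
sumSamples <- function(signals) {
    stopifnot(length(signals) >= 1)
    org <- signals[[1]]@origin
    for (s in signals[-1])
        if (!identical(s@origin, org))
            stop("all signals must share the same layout and mask")
    v <- numeric(length(org))
    supp <- integer(length(org))
    for (s in signals) {
        v <- v + s@values
        supp <- supp + (s@values != 0)
    }
    new("SumSignal", values = v, support = supp,
        nSamples = length(signals), origin = org,
        junctions = signals[[1]]@junctions, layout = signals[[1]]@layout)
}

#' @describeIn sumSamples Per-position patient support.
#' @param x a `SumSignal`.
#' @export
setGeneric("patientSupport", function(x) standardGeneric("patientSupport"))

#' @rdname sumSamples
#' @export
setMethod("patientSupport", "SumSignal", function(x) x@support)

setMethod("show", "SumSignal", function(object) {
    cat("SumSignal over", object@nSamples, "samples:",
        format(length(object@values), big.mark = ","), "positions,",
        sum(object@values != 0), "nonzero\n")
})

#' Maximal same-sign nonzero runs of the recurrence signal
#'
#' Runs never span a sign change or a chromosome boundary.  Each run
#' carries its concatenated span, sign, value sum, and maximum
#' per-position patient support.
#'
#' @param sum a [SumSignal-class] (or any [MaskedSignal-class]; support
#'   then counts nothing and is 0).
#' @return data.frame with columns `start`, `end` (concatenated, 1-based
#'   inclusive), `sign`, `chrom` (layout chromosome id), `score`,
#'   `support`.
#' @export
extractRuns <- function(sum) {
    supp <- if (is(sum, "SumSignal")) sum@support
            else integer(length(sum@values))
    ch <- chromOfBin(sum@layout, sum@origin)
    cpp_extract_runs(sum@values, as.integer(supp), ch)
}

#' Count maximal same-sign nonzero segments of a signal
#'
#' A segment is a consecutive stretch with the same nonzero sign; this is
#' the per-sample fragmentation measure used to check that thresholding
#' controls excessive read-depth changes.
#'
#' @param values numeric per-position signal (or a [MaskedSignal-class]).
#' @return integer count.
#' @examples
#' countSignSegments(c(0, 1, 1, -1, 0, 2))  # 3
#' @export
countSignSegments <- function(values) {
    if (is(values, "MaskedSignal")) return(nrow(extractRuns(values)))
    r <- rle(sign(values))
    sum(r$values != 0)
}

# core grouping/scoring on a run table, in concatenated-bin units.
# Same-sign runs on the same chromosome merge into groups when their
# end-to-start gaps (exclusive) are <= dBins; within a group, subgroups
# form with gaps <= rBins; each group emits its max-|score| subgroup
# (ties: leftmost).
clusterRuns <- function(runs, dBins, rBins) {
    out <- list()
    if (nrow(runs) == 0L)
        return(data.frame(start = integer(), end = integer(),
                          sign = integer(), chrom = integer(),
                          score = numeric(), support = integer(),
                          nRuns = integer()))
    for (key in split(seq_len(nrow(runs)),
                      list(runs$chrom, runs$sign), drop = TRUE)) {
        rr <- runs[key[order(runs$start[key])], , drop = FALSE]
        gap <- rr$start[-1] - rr$end[-nrow(rr)] - 1L
        grp <- cumsum(c(1L, as.integer(gap > dBins)))
        for (g in split(seq_len(nrow(rr)), grp)) {
            sub <- cumsum(c(1L, as.integer(
                (rr$start[g][-1] - rr$end[g][-length(g)] - 1L) > rBins)))
            scores <- vapply(seq_len(max(sub)), function(sv)
                sum(rr$score[g[sub == sv]]), numeric(1))
            win <- which(abs(scores) == max(abs(scores)))[1]  # leftmost tie
            ii <- g[sub == win]
            out[[length(out) + 1L]] <- data.frame(
                start = rr$start[ii[1]], end = rr$end[ii[length(ii)]],
                sign = rr$sign[ii[1]], chrom = rr$chrom[ii[1]],
                score = scores[win], support = max(rr$support[ii]),
                nRuns = length(ii))
        }
    }
    res <- do.call(rbind, out)
    res[order(-abs(res$score)), , drop = FALSE]
}

#' Group runs into candidate focal clusters
#'
#' Same-sign runs whose mutual gaps are at most `d` merge into groups;
#' within a group, runs with gaps at most `r` merge into subgroups whose
#' score is the sum of their runs' signal sums.  Each group emits its
#' maximum-|score| subgroup as one cluster (ties broken leftmost).  Gaps
#' are measured end-to-start, exclusive, in concatenated-bin units
#' converted to bp via the bin size; opposite-sign runs never share a
#' group.
#'
#' @param sum a [SumSignal-class], or a run data.frame from
#'   [extractRuns()] (then `signal` must supply the coordinate map).
#' @param d,r grouping / subgrouping distances in bp (default 3e5).
#' @param signal the [MaskedSignal-class] carrying the coordinate map
#'   when `sum` is a run table.
#' @return `GRanges` of clusters, 1-based inclusive genomic coordinates
#'   at bin boundaries, sorted by `|score|` descending, with metadata
#'   columns `score`, `sign`, `nPatients`, `nRuns`, `lengthBp`
#'   (concatenated span times bin size, the scale used in significance
#'   comparisons), and `spansJunction`.
#' @export
groupAndCluster <- function(sum, d = 3e5, r = 3e5, signal = sum) {
    stopifnot(d >= 0, r >= 0)
    runs <- if (is.data.frame(sum)) sum else extractRuns(sum)
    bs <- binSize(signal@layout)
    cl <- clusterRuns(runs, dBins = floor(d / bs), rBins = floor(r / bs))
    if (nrow(cl) == 0L)
        return(GenomicRanges::GRanges(score = numeric(), sign = integer(),
                                      nPatients = integer()))
    gspan <- concatenatedSpan(signal, cl$start, cl$end)
    junc <- vapply(seq_len(nrow(cl)), function(i)
        any(signal@junctions > cl$start[i] & signal@junctions <= cl$end[i]),
        logical(1))
    gr <- GenomicRanges::GRanges(gspan$chrom,
                                 IRanges::IRanges(gspan$start, gspan$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        score = cl$score, sign = cl$sign, nPatients = cl$support,
        nRuns = cl$nRuns, lengthBp = (cl$end - cl$start + 1) * bs,
        spansJunction = junc)
    gr
}

#' Attach overlapping gene names to clusters
#'
#' Genes whose interval overlaps a cluster by at least one bp are listed
#' in a `genes` metadata column (order of the annotation preserved,
#' duplicates collapsed).
#'
#' @param clusters `GRanges` from [groupAndCluster()].
#' @param geneBed path to a named BED file, or a `GRanges` with a `name`
#'   column.
#' @return `clusters` with a `genes` character column (`""` when none).
#' @export
annotateClusters <- function(clusters, geneBed) {
    genes <- if (is.character(geneBed)) {
        tryCatch(rtracklayer::import(geneBed, format = "BED"),
                 error = function(e)
                     stop("malformed BED '", geneBed, "': ",
                          conditionMessage(e)))
    } else geneBed
    if (is.null(genes$name)) stop("gene annotation must carry names")
    hits <- GenomicRanges::findOverlaps(clusters, genes)
    ann <- rep("", length(clusters))
    for (i in unique(S4Vectors::queryHits(hits))) {
        g <- genes$name[S4Vectors::subjectHits(hits)[
            S4Vectors::queryHits(hits) == i]]
        ann[i] <- paste(unique(g), collapse = "|")
    }
    clusters$genes <- ann
    clusters
}
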